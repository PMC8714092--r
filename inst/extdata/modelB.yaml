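n_envs: 5
n_objects: 9
p_max:
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
tau:
- 2.8
- 1.4
- 0.7
- 0.35
- 0.175
size_dist:
- - 0.2
  - 0.2
  - 0.2
  - 0.2
  - 0.2
- - 0.2
  - 0.2
  - 0.2
  - 0.2
  - 0.2
- - 0.2
  - 0.2
  - 0.2
  - 0.2
  - 0.2
- - 0.2
  - 0.2
  - 0.2
  - 0.2
  - 0.2
- - 0.2
  - 0.2
  - 0.2
  - 0.2
  - 0.2
max_size: 5
t_inspect: 0.5
t_consume: 1.25
t_travel: 8.0
k: 0.275
T_max: 23.75
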