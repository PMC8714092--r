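n_envs: 5
n_objects: 9
p_max:
- 0.2
- 0.2
- 0.2
- 0.2
- 0.2
tau:
- 0.0
- 0.0
- 0.0
- 0.0
- 0.0
size_dist:
- - 0.636408646558831
  - 0.234121657252737
  - 0.086128544436269
  - 0.031684920796124
  - 0.01165623095604
- - 0.428655528777167
  - 0.259992720658683
  - 0.157693556381593
  - 0.095645976784559
  - 0.058012217397998
- - 0.2
  - 0.2
  - 0.2
  - 0.2
  - 0.2
- - 0.058012217397998
  - 0.095645976784559
  - 0.157693556381593
  - 0.259992720658683
  - 0.428655528777167
- - 0.01165623095604
  - 0.031684920796124
  - 0.086128544436269
  - 0.234121657252737
  - 0.636408646558831
max_size: 5
t_inspect: 0.5
t_consume: 1.25
t_travel: 8.0
k: 0.275
T_max: 23.75
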