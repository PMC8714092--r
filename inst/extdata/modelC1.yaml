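n_envs: 5
n_objects: 9
p_max:
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
tau:
- 0.7
- 0.7
- 0.7
- 0.7
- 0.7
size_dist:
- - 0.560945103841136
  - 0.252048882435565
  - 0.113252863251676
  - 0.050887791728185
  - 0.022865358743438
- - 0.381280683220681
  - 0.255580085128987
  - 0.171320454429455
  - 0.114839534899999
  - 0.076979242320879
- - 0.2
  - 0.2
  - 0.2
  - 0.2
  - 0.2
- - 0.076979242320879
  - 0.114839534899999
  - 0.171320454429455
  - 0.255580085128987
  - 0.381280683220681
- - 0.022865358743438
  - 0.050887791728185
  - 0.113252863251676
  - 0.252048882435565
  - 0.560945103841136
max_size: 5
t_inspect: 0.5
t_consume: 1.25
t_travel: 8.0
k: 0.275
T_max: 23.75
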