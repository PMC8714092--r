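n_envs: 5
n_objects: 9
p_max:
- 0.366666666666667
- 0.433333333333333
- 0.5
- 0.566666666666667
- 0.633333333333333
tau:
- 1.11118073637774
- 0.881944734926411
- 0.7
- 0.55559036818887
- 0.440972367463206
size_dist:
- - 0.317858163989776
  - 0.243456575380327
  - 0.186470290245002
  - 0.142822879561728
  - 0.109392090823169
- - 0.256537346132844
  - 0.224514640673551
  - 0.196489223252006
  - 0.171962125669629
  - 0.15049666427197
- - 0.2
  - 0.2
  - 0.2
  - 0.2
  - 0.2
- - 0.15049666427197
  - 0.171962125669629
  - 0.196489223252006
  - 0.224514640673551
  - 0.256537346132844
- - 0.109392090823169
  - 0.142822879561728
  - 0.186470290245002
  - 0.243456575380327
  - 0.317858163989776
max_size: 5
t_inspect: 0.5
t_consume: 1.25
t_travel: 8.0
k: 0.275
T_max: 23.75
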