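# Efficient consumer in a temperature-independent chemostat.
model: chemostat
delta: 0.5
m_a: 0.01
m_b: 0.1
m_c: 0.05
T_I: 25.0
beta: 150.0
R_0: 0.5
S: 1.0
D: 1.0
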