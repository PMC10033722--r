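# Synthetic muscle dispersion table: a log-log power-law anchored at the
# reported eps_r(10 Hz) = 1e8; intermediate points are illustrative, not
# measured data.
frequency_Hz	eps_r
10	1e8
100	1e7
1000	1e6
10000	1e5
100000	1e4
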