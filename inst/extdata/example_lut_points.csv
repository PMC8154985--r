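"I","z"
40.6854792235733,0
64.9256831591999,33.2857142857143
91.0851217566891,66.5714285714286
117.403007220848,99.8571428571429
143.959221508509,133.142857142857
170.862029578689,166.428571428571
199.316350386475,199.714285714286
226.646250480793,233
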