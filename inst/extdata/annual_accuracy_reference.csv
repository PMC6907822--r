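year,users_accuracy_pct,producers_accuracy_pct
2004,94.7,86.1
2005,93.8,92.1
2006,96.4,92.9
2007,93.9,84.1
2008,93.2,92.8
2009,93.7,91.6
2010,94.1,91.3
2011,93.2,92.2
2012,96.1,91.7
2013,95.7,92.2
2014,91.8,84.4
2015,95.9,93.3
2016,95.8,88.4
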