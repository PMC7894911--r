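stress
0.39
0.85
1.08
1.25
1.47
1.57
1.61
1.61
1.69
1.80
1.84
1.87
1.89
2.03
2.03
2.05
2.12
2.35
2.41
2.43
2.48
2.50
2.53
2.55
2.55
2.56
2.59
2.67
2.73
2.74
2.79
2.81
2.82
2.85
2.87
2.88
2.93
2.95
2.96
2.97
3.09
3.11
3.11
3.15
3.15
3.19
3.22
3.22
3.27
3.28
3.31
3.31
3.33
3.39
3.39
3.56
3.60
3.65
3.68
3.70
3.75
4.20
4.38
4.42
4.70
4.90
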