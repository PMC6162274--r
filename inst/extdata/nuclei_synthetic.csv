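x_um,y_um
48.75,150.88
33.17,153.41
154.56,138.75
19.26,145.6
127.89,55.3
59.04,37.21
199.34,158.34
136,44.9
37.14,134.38
151.94,38.17
154.81,37.4
144.6,137.3
144.56,150.67
70.99,50.16
153.08,146.2
36.82,54.95
64.24,150.49
173.27,58.54
155.73,39.7
151.65,48.9
161.1,85.61
143.8,68.79
38.61,27.32
193.42,174.05
198.46,148.05
169.2,130.24
161.85,19.71
146.41,50.58
160.27,36.71
144.32,20.43
24.03,136.35
124.25,57.63
144.6,13.62
58.01,138.68
48.44,10.33
152.24,62.12
147.95,44.99
113.29,161.98
49.48,28.08
164.07,158.01
53.4,162.65
146.17,33.87
146.95,198.02
156.56,168.64
20.9,173.68
155.39,168.02
76.27,167.34
76.67,53.31
150.92,125.42
140.83,34.62
73.13,49.08
149.44,160.05
102.18,46.46
145.94,153.73
145.5,51.61
157.2,38.65
50.52,156.5
138.01,129.28
96.51,172.79
55.33,120.85
164.17,180.62
144.26,140.25
119.86,55.78
165.73,15.13
24.3,24.08
58.34,62.06
23.91,65.13
156.82,32.94
47.33,50.51
143.81,154.79
170.12,93.53
53.2,146.54
148.16,34.91
66.59,70.17
46.08,150.32
168.17,27.75
54.67,145.38
179.53,74.55
35.23,146.07
45.13,170.95
42,62.18
63.79,148.17
167.06,55.92
153.03,43.99
164.29,189.42
49.96,45.38
173.16,63.89
143.7,47.51
55.53,149.24
102.54,57.91
131.45,155.93
48.74,132.49
43.42,153.83
95.4,32.96
42.39,57
102.13,129.91
171.53,148.09
154.24,40.97
26.21,132.63
87.1,151.3
157.31,148.62
157.31,136.67
36.74,36.2
49.16,131.63
38.87,142.6
141.12,38.82
142.22,55.26
166.32,36.21
127.81,139.65
154.08,157.72
181.99,148.08
143.97,159.27
52.27,59.44
170.15,21.12
63.84,76.6
146.55,175.66
166.35,72.75
47.77,146.58
45.22,46.48
130.66,163.15
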