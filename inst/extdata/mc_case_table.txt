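0:
1: 9 4 1
2: 1 2 10
3: 10 9 4; 10 4 2
4: 2 3 12
5: 9 4 1; 2 3 12
6: 1 3 12; 1 12 10
7: 12 10 9; 12 9 4; 12 4 3
8: 3 4 11
9: 9 11 3; 9 3 1
10: 1 2 10; 3 4 11
11: 10 9 11; 10 11 3; 10 3 2
12: 2 4 11; 2 11 12
13: 9 11 12; 9 12 2; 9 2 1
14: 1 4 11; 1 11 12; 1 12 10
15: 11 12 10; 11 10 9
16: 5 8 9
17: 5 8 4; 5 4 1
18: 1 2 10; 5 8 9
19: 10 5 8; 10 8 4; 10 4 2
20: 2 3 12; 5 8 9
21: 5 8 4; 5 4 1; 2 3 12
22: 1 3 12; 1 12 10; 5 8 9
23: 12 10 5; 12 5 8; 12 8 4; 12 4 3
24: 3 4 11; 5 8 9
25: 5 8 11; 5 11 3; 5 3 1
26: 1 2 10; 3 4 11; 5 8 9
27: 10 5 8; 10 8 11; 10 11 3; 10 3 2
28: 2 4 11; 2 11 12; 5 8 9
29: 5 8 11; 5 11 12; 5 12 2; 5 2 1
30: 1 4 11; 1 11 12; 1 12 10; 5 8 9
31: 5 8 11; 5 11 12; 5 12 10
32: 10 6 5
33: 9 4 1; 10 6 5
34: 1 2 6; 1 6 5
35: 6 5 9; 6 9 4; 6 4 2
36: 2 3 12; 10 6 5
37: 9 4 1; 2 3 12; 10 6 5
38: 1 3 12; 1 12 6; 1 6 5
39: 12 6 5; 12 5 9; 12 9 4; 12 4 3
40: 3 4 11; 10 6 5
41: 9 11 3; 9 3 1; 10 6 5
42: 1 2 6; 1 6 5; 3 4 11
43: 6 5 9; 6 9 11; 6 11 3; 6 3 2
44: 2 4 11; 2 11 12; 10 6 5
45: 9 11 12; 9 12 2; 9 2 1; 10 6 5
46: 1 4 11; 1 11 12; 1 12 6; 1 6 5
47: 9 11 12; 9 12 6; 9 6 5
48: 6 8 9; 6 9 10
49: 10 6 8; 10 8 4; 10 4 1
50: 1 2 6; 1 6 8; 1 8 9
51: 6 8 4; 6 4 2
52: 2 3 12; 6 8 9; 6 9 10
53: 10 6 8; 10 8 4; 10 4 1; 2 3 12
54: 1 3 12; 1 12 6; 1 6 8; 1 8 9
55: 12 6 8; 12 8 4; 12 4 3
56: 3 4 11; 6 8 9; 6 9 10
57: 10 6 8; 10 8 11; 10 11 3; 10 3 1
58: 1 2 6; 1 6 8; 1 8 9; 3 4 11
59: 6 8 11; 6 11 3; 6 3 2
60: 2 4 11; 2 11 12; 6 8 9; 6 9 10
61: 10 6 8; 10 8 11; 10 11 12; 10 12 2; 10 2 1
62: 1 4 11; 1 11 12; 1 12 6; 1 6 8; 1 8 9
63: 6 8 11; 6 11 12
64: 12 7 6
65: 9 4 1; 12 7 6
66: 1 2 10; 12 7 6
67: 10 9 4; 10 4 2; 12 7 6
68: 2 3 7; 2 7 6
69: 9 4 1; 2 3 7; 2 7 6
70: 1 3 7; 1 7 6; 1 6 10
71: 7 6 10; 7 10 9; 7 9 4; 7 4 3
72: 3 4 11; 12 7 6
73: 9 11 3; 9 3 1; 12 7 6
74: 1 2 10; 3 4 11; 12 7 6
75: 10 9 11; 10 11 3; 10 3 2; 12 7 6
76: 2 4 11; 2 11 7; 2 7 6
77: 9 11 7; 9 7 6; 9 6 2; 9 2 1
78: 1 4 11; 1 11 7; 1 7 6; 1 6 10
79: 10 9 11; 10 11 7; 10 7 6
80: 5 8 9; 12 7 6
81: 5 8 4; 5 4 1; 12 7 6
82: 1 2 10; 5 8 9; 12 7 6
83: 10 5 8; 10 8 4; 10 4 2; 12 7 6
84: 2 3 7; 2 7 6; 5 8 9
85: 5 8 4; 5 4 1; 2 3 7; 2 7 6
86: 1 3 7; 1 7 6; 1 6 10; 5 8 9
87: 7 6 10; 7 10 5; 7 5 8; 7 8 4; 7 4 3
88: 3 4 11; 5 8 9; 12 7 6
89: 5 8 11; 5 11 3; 5 3 1; 12 7 6
90: 1 2 10; 3 4 11; 5 8 9; 12 7 6
91: 10 5 8; 10 8 11; 10 11 3; 10 3 2; 12 7 6
92: 2 4 11; 2 11 7; 2 7 6; 5 8 9
93: 5 8 11; 5 11 7; 5 7 6; 5 6 2; 5 2 1
94: 1 4 11; 1 11 7; 1 7 6; 1 6 10; 5 8 9
95: 5 8 11; 5 11 7; 5 7 6; 5 6 10
96: 10 12 7; 10 7 5
97: 9 4 1; 10 12 7; 10 7 5
98: 1 2 12; 1 12 7; 1 7 5
99: 12 7 5; 12 5 9; 12 9 4; 12 4 2
100: 2 3 7; 2 7 5; 2 5 10
101: 9 4 1; 2 3 7; 2 7 5; 2 5 10
102: 1 3 7; 1 7 5
103: 7 5 9; 7 9 4; 7 4 3
104: 3 4 11; 10 12 7; 10 7 5
105: 9 11 3; 9 3 1; 10 12 7; 10 7 5
106: 1 2 12; 1 12 7; 1 7 5; 3 4 11
107: 12 7 5; 12 5 9; 12 9 11; 12 11 3; 12 3 2
108: 2 4 11; 2 11 7; 2 7 5; 2 5 10
109: 9 11 7; 9 7 5; 9 5 10; 9 10 2; 9 2 1
110: 1 4 11; 1 11 7; 1 7 5
111: 9 11 7; 9 7 5
112: 7 8 9; 7 9 10; 7 10 12
113: 10 12 7; 10 7 8; 10 8 4; 10 4 1
114: 1 2 12; 1 12 7; 1 7 8; 1 8 9
115: 12 7 8; 12 8 4; 12 4 2
116: 2 3 7; 2 7 8; 2 8 9; 2 9 10
117: 10 2 3; 10 3 7; 10 7 8; 10 8 4; 10 4 1
118: 1 3 7; 1 7 8; 1 8 9
119: 7 8 4; 7 4 3
120: 3 4 11; 7 8 9; 7 9 10; 7 10 12
121: 10 12 7; 10 7 8; 10 8 11; 10 11 3; 10 3 1
122: 1 2 12; 1 12 7; 1 7 8; 1 8 9; 3 4 11
123: 12 7 8; 12 8 11; 12 11 3; 12 3 2
124: 2 4 11; 2 11 7; 2 7 8; 2 8 9; 2 9 10
125: 10 2 1; 7 8 11
126: 1 4 11; 1 11 7; 1 7 8; 1 8 9
127: 7 8 11
128: 11 8 7
129: 9 4 1; 11 8 7
130: 1 2 10; 11 8 7
131: 10 9 4; 10 4 2; 11 8 7
132: 2 3 12; 11 8 7
133: 9 4 1; 2 3 12; 11 8 7
134: 1 3 12; 1 12 10; 11 8 7
135: 12 10 9; 12 9 4; 12 4 3; 11 8 7
136: 3 4 8; 3 8 7
137: 9 8 7; 9 7 3; 9 3 1
138: 1 2 10; 3 4 8; 3 8 7
139: 10 9 8; 10 8 7; 10 7 3; 10 3 2
140: 2 4 8; 2 8 7; 2 7 12
141: 9 8 7; 9 7 12; 9 12 2; 9 2 1
142: 1 4 8; 1 8 7; 1 7 12; 1 12 10
143: 12 10 9; 12 9 8; 12 8 7
144: 5 7 11; 5 11 9
145: 5 7 11; 5 11 4; 5 4 1
146: 1 2 10; 5 7 11; 5 11 9
147: 10 5 7; 10 7 11; 10 11 4; 10 4 2
148: 2 3 12; 5 7 11; 5 11 9
149: 5 7 11; 5 11 4; 5 4 1; 2 3 12
150: 1 3 12; 1 12 10; 5 7 11; 5 11 9
151: 12 10 5; 12 5 7; 12 7 11; 12 11 4; 12 4 3
152: 3 4 9; 3 9 5; 3 5 7
153: 5 7 3; 5 3 1
154: 1 2 10; 3 4 9; 3 9 5; 3 5 7
155: 10 5 7; 10 7 3; 10 3 2
156: 2 4 9; 2 9 5; 2 5 7; 2 7 12
157: 5 7 12; 5 12 2; 5 2 1
158: 1 4 9; 1 9 5; 1 5 7; 1 7 12; 1 12 10
159: 5 7 12; 5 12 10
160: 10 6 5; 11 8 7
161: 9 4 1; 10 6 5; 11 8 7
162: 1 2 6; 1 6 5; 11 8 7
163: 6 5 9; 6 9 4; 6 4 2; 11 8 7
164: 2 3 12; 10 6 5; 11 8 7
165: 9 4 1; 2 3 12; 10 6 5; 11 8 7
166: 1 3 12; 1 12 6; 1 6 5; 11 8 7
167: 12 6 5; 12 5 9; 12 9 4; 12 4 3; 11 8 7
168: 3 4 8; 3 8 7; 10 6 5
169: 9 8 7; 9 7 3; 9 3 1; 10 6 5
170: 1 2 6; 1 6 5; 3 4 8; 3 8 7
171: 6 5 9; 6 9 8; 6 8 7; 6 7 3; 6 3 2
172: 2 4 8; 2 8 7; 2 7 12; 10 6 5
173: 9 8 7; 9 7 12; 9 12 2; 9 2 1; 10 6 5
174: 1 4 8; 1 8 7; 1 7 12; 1 12 6; 1 6 5
175: 9 8 7; 9 7 12; 9 12 6; 9 6 5
176: 6 7 11; 6 11 9; 6 9 10
177: 10 6 7; 10 7 11; 10 11 4; 10 4 1
178: 1 2 6; 1 6 7; 1 7 11; 1 11 9
179: 6 7 11; 6 11 4; 6 4 2
180: 2 3 12; 6 7 11; 6 11 9; 6 9 10
181: 10 6 7; 10 7 11; 10 11 4; 10 4 1; 2 3 12
182: 1 3 12; 1 12 6; 1 6 7; 1 7 11; 1 11 9
183: 12 6 7; 12 7 11; 12 11 4; 12 4 3
184: 3 4 9; 3 9 10; 3 10 6; 3 6 7
185: 10 6 7; 10 7 3; 10 3 1
186: 1 2 6; 1 6 7; 1 7 3; 1 3 4; 1 4 9
187: 6 7 3; 6 3 2
188: 2 4 9; 2 9 10; 2 10 6; 2 6 7; 2 7 12
189: 10 6 7; 10 7 12; 10 12 2; 10 2 1
190: 1 4 9; 6 7 12
191: 6 7 12
192: 12 11 8; 12 8 6
193: 9 4 1; 12 11 8; 12 8 6
194: 1 2 10; 12 11 8; 12 8 6
195: 10 9 4; 10 4 2; 12 11 8; 12 8 6
196: 2 3 11; 2 11 8; 2 8 6
197: 9 4 1; 2 3 11; 2 11 8; 2 8 6
198: 1 3 11; 1 11 8; 1 8 6; 1 6 10
199: 11 8 6; 11 6 10; 11 10 9; 11 9 4; 11 4 3
200: 3 4 8; 3 8 6; 3 6 12
201: 9 8 6; 9 6 12; 9 12 3; 9 3 1
202: 1 2 10; 3 4 8; 3 8 6; 3 6 12
203: 10 9 8; 10 8 6; 10 6 12; 10 12 3; 10 3 2
204: 2 4 8; 2 8 6
205: 9 8 6; 9 6 2; 9 2 1
206: 1 4 8; 1 8 6; 1 6 10
207: 10 9 8; 10 8 6
208: 5 6 12; 5 12 11; 5 11 9
209: 5 6 12; 5 12 11; 5 11 4; 5 4 1
210: 1 2 10; 5 6 12; 5 12 11; 5 11 9
211: 10 5 6; 10 6 12; 10 12 11; 10 11 4; 10 4 2
212: 2 3 11; 2 11 9; 2 9 5; 2 5 6
213: 5 6 2; 5 2 3; 5 3 11; 5 11 4; 5 4 1
214: 1 3 11; 1 11 9; 1 9 5; 1 5 6; 1 6 10
215: 11 4 3; 5 6 10
216: 3 4 9; 3 9 5; 3 5 6; 3 6 12
217: 5 6 12; 5 12 3; 5 3 1
218: 1 2 10; 3 4 9; 3 9 5; 3 5 6; 3 6 12
219: 10 5 6; 10 6 12; 10 12 3; 10 3 2
220: 2 4 9; 2 9 5; 2 5 6
221: 5 6 2; 5 2 1
222: 1 4 9; 1 9 5; 1 5 6; 1 6 10
223: 5 6 10
224: 10 12 11; 10 11 8; 10 8 5
225: 9 4 1; 10 12 11; 10 11 8; 10 8 5
226: 1 2 12; 1 12 11; 1 11 8; 1 8 5
227: 12 11 8; 12 8 5; 12 5 9; 12 9 4; 12 4 2
228: 2 3 11; 2 11 8; 2 8 5; 2 5 10
229: 9 4 1; 2 3 11; 2 11 8; 2 8 5; 2 5 10
230: 1 3 11; 1 11 8; 1 8 5
231: 11 8 5; 11 5 9; 11 9 4; 11 4 3
232: 3 4 8; 3 8 5; 3 5 10; 3 10 12
233: 9 8 5; 9 5 10; 9 10 12; 9 12 3; 9 3 1
234: 1 2 12; 1 12 3; 1 3 4; 1 4 8; 1 8 5
235: 12 3 2; 9 8 5
236: 2 4 8; 2 8 5; 2 5 10
237: 9 8 5; 9 5 10; 9 10 2; 9 2 1
238: 1 4 8; 1 8 5
239: 9 8 5
240: 9 10 12; 9 12 11
241: 10 12 11; 10 11 4; 10 4 1
242: 1 2 12; 1 12 11; 1 11 9
243: 12 11 4; 12 4 2
244: 2 3 11; 2 11 9; 2 9 10
245: 10 2 3; 10 3 11; 10 11 4; 10 4 1
246: 1 3 11; 1 11 9
247: 11 4 3
248: 3 4 9; 3 9 10; 3 10 12
249: 10 12 3; 10 3 1
250: 1 2 12; 1 12 3; 1 3 4; 1 4 9
251: 12 3 2
252: 2 4 9; 2 9 10
253: 10 2 1
254: 1 4 9
255:
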