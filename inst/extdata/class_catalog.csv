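class_id,bone,grade,class_label
0,radius,0,radius_0
1,radius,1,radius_1
2,radius,2,radius_2
3,radius,3,radius_3
4,radius,4,radius_4
5,radius,5,radius_5
6,radius,6,radius_6
7,radius,7,radius_7
8,radius,8,radius_8
9,radius,9,radius_9
10,radius,10,radius_10
11,radius,11,radius_11
12,radius,12,radius_12
13,radius,13,radius_13
14,radius,14,radius_14
15,ulna,0,ulna_0
16,ulna,1,ulna_1
17,ulna,2,ulna_2
18,ulna,3,ulna_3
19,ulna,4,ulna_4
20,ulna,5,ulna_5
21,ulna,6,ulna_6
22,ulna,7,ulna_7
23,ulna,8,ulna_8
24,ulna,9,ulna_9
25,ulna,10,ulna_10
26,ulna,11,ulna_11
27,ulna,12,ulna_12
28,first_metacarpal,0,first_metacarpal_0
29,first_metacarpal,1,first_metacarpal_1
30,first_metacarpal,2,first_metacarpal_2
31,first_metacarpal,3,first_metacarpal_3
32,first_metacarpal,4,first_metacarpal_4
33,first_metacarpal,5,first_metacarpal_5
34,first_metacarpal,6,first_metacarpal_6
35,first_metacarpal,7,first_metacarpal_7
36,first_metacarpal,8,first_metacarpal_8
37,first_metacarpal,9,first_metacarpal_9
38,first_metacarpal,10,first_metacarpal_10
39,first_metacarpal,11,first_metacarpal_11
40,third_metacarpal,0,third_metacarpal_0
41,third_metacarpal,1,third_metacarpal_1
42,third_metacarpal,2,third_metacarpal_2
43,third_metacarpal,3,third_metacarpal_3
44,third_metacarpal,4,third_metacarpal_4
45,third_metacarpal,5,third_metacarpal_5
46,third_metacarpal,6,third_metacarpal_6
47,third_metacarpal,7,third_metacarpal_7
48,third_metacarpal,8,third_metacarpal_8
49,third_metacarpal,9,third_metacarpal_9
50,third_metacarpal,10,third_metacarpal_10
51,fifth_metacarpal,0,fifth_metacarpal_0
52,fifth_metacarpal,1,fifth_metacarpal_1
53,fifth_metacarpal,2,fifth_metacarpal_2
54,fifth_metacarpal,3,fifth_metacarpal_3
55,fifth_metacarpal,4,fifth_metacarpal_4
56,fifth_metacarpal,5,fifth_metacarpal_5
57,fifth_metacarpal,6,fifth_metacarpal_6
58,fifth_metacarpal,7,fifth_metacarpal_7
59,fifth_metacarpal,8,fifth_metacarpal_8
60,fifth_metacarpal,9,fifth_metacarpal_9
61,fifth_metacarpal,10,fifth_metacarpal_10
62,first_proximal_phalange,0,first_proximal_phalange_0
63,first_proximal_phalange,1,first_proximal_phalange_1
64,first_proximal_phalange,2,first_proximal_phalange_2
65,first_proximal_phalange,3,first_proximal_phalange_3
66,first_proximal_phalange,4,first_proximal_phalange_4
67,first_proximal_phalange,5,first_proximal_phalange_5
68,first_proximal_phalange,6,first_proximal_phalange_6
69,first_proximal_phalange,7,first_proximal_phalange_7
70,first_proximal_phalange,8,first_proximal_phalange_8
71,first_proximal_phalange,9,first_proximal_phalange_9
72,first_proximal_phalange,10,first_proximal_phalange_10
73,first_proximal_phalange,11,first_proximal_phalange_11
74,first_proximal_phalange,12,first_proximal_phalange_12
75,third_proximal_phalange,0,third_proximal_phalange_0
76,third_proximal_phalange,1,third_proximal_phalange_1
77,third_proximal_phalange,2,third_proximal_phalange_2
78,third_proximal_phalange,3,third_proximal_phalange_3
79,third_proximal_phalange,4,third_proximal_phalange_4
80,third_proximal_phalange,5,third_proximal_phalange_5
81,third_proximal_phalange,6,third_proximal_phalange_6
82,third_proximal_phalange,7,third_proximal_phalange_7
83,third_proximal_phalange,8,third_proximal_phalange_8
84,third_proximal_phalange,9,third_proximal_phalange_9
85,third_proximal_phalange,10,third_proximal_phalange_10
86,third_proximal_phalange,11,third_proximal_phalange_11
87,third_proximal_phalange,12,third_proximal_phalange_12
88,fifth_proximal_phalange,0,fifth_proximal_phalange_0
89,fifth_proximal_phalange,1,fifth_proximal_phalange_1
90,fifth_proximal_phalange,2,fifth_proximal_phalange_2
91,fifth_proximal_phalange,3,fifth_proximal_phalange_3
92,fifth_proximal_phalange,4,fifth_proximal_phalange_4
93,fifth_proximal_phalange,5,fifth_proximal_phalange_5
94,fifth_proximal_phalange,6,fifth_proximal_phalange_6
95,fifth_proximal_phalange,7,fifth_proximal_phalange_7
96,fifth_proximal_phalange,8,fifth_proximal_phalange_8
97,fifth_proximal_phalange,9,fifth_proximal_phalange_9
98,fifth_proximal_phalange,10,fifth_proximal_phalange_10
99,fifth_proximal_phalange,11,fifth_proximal_phalange_11
100,fifth_proximal_phalange,12,fifth_proximal_phalange_12
101,third_middle_phalange,0,third_middle_phalange_0
102,third_middle_phalange,1,third_middle_phalange_1
103,third_middle_phalange,2,third_middle_phalange_2
104,third_middle_phalange,3,third_middle_phalange_3
105,third_middle_phalange,4,third_middle_phalange_4
106,third_middle_phalange,5,third_middle_phalange_5
107,third_middle_phalange,6,third_middle_phalange_6
108,third_middle_phalange,7,third_middle_phalange_7
109,third_middle_phalange,8,third_middle_phalange_8
110,third_middle_phalange,9,third_middle_phalange_9
111,third_middle_phalange,10,third_middle_phalange_10
112,third_middle_phalange,11,third_middle_phalange_11
113,third_middle_phalange,12,third_middle_phalange_12
114,fifth_middle_phalange,0,fifth_middle_phalange_0
115,fifth_middle_phalange,1,fifth_middle_phalange_1
116,fifth_middle_phalange,2,fifth_middle_phalange_2
117,fifth_middle_phalange,3,fifth_middle_phalange_3
118,fifth_middle_phalange,4,fifth_middle_phalange_4
119,fifth_middle_phalange,5,fifth_middle_phalange_5
120,fifth_middle_phalange,6,fifth_middle_phalange_6
121,fifth_middle_phalange,7,fifth_middle_phalange_7
122,fifth_middle_phalange,8,fifth_middle_phalange_8
123,fifth_middle_phalange,9,fifth_middle_phalange_9
124,fifth_middle_phalange,10,fifth_middle_phalange_10
125,fifth_middle_phalange,11,fifth_middle_phalange_11
126,fifth_middle_phalange,12,fifth_middle_phalange_12
127,first_distal_phalange,0,first_distal_phalange_0
128,first_distal_phalange,1,first_distal_phalange_1
129,first_distal_phalange,2,first_distal_phalange_2
130,first_distal_phalange,3,first_distal_phalange_3
131,first_distal_phalange,4,first_distal_phalange_4
132,first_distal_phalange,5,first_distal_phalange_5
133,first_distal_phalange,6,first_distal_phalange_6
134,first_distal_phalange,7,first_distal_phalange_7
135,first_distal_phalange,8,first_distal_phalange_8
136,first_distal_phalange,9,first_distal_phalange_9
137,first_distal_phalange,10,first_distal_phalange_10
138,first_distal_phalange,11,first_distal_phalange_11
139,third_distal_phalange,0,third_distal_phalange_0
140,third_distal_phalange,1,third_distal_phalange_1
141,third_distal_phalange,2,third_distal_phalange_2
142,third_distal_phalange,3,third_distal_phalange_3
143,third_distal_phalange,4,third_distal_phalange_4
144,third_distal_phalange,5,third_distal_phalange_5
145,third_distal_phalange,6,third_distal_phalange_6
146,third_distal_phalange,7,third_distal_phalange_7
147,third_distal_phalange,8,third_distal_phalange_8
148,third_distal_phalange,9,third_distal_phalange_9
149,third_distal_phalange,10,third_distal_phalange_10
150,third_distal_phalange,11,third_distal_phalange_11
151,fifth_distal_phalange,0,fifth_distal_phalange_0
152,fifth_distal_phalange,1,fifth_distal_phalange_1
153,fifth_distal_phalange,2,fifth_distal_phalange_2
154,fifth_distal_phalange,3,fifth_distal_phalange_3
155,fifth_distal_phalange,4,fifth_distal_phalange_4
156,fifth_distal_phalange,5,fifth_distal_phalange_5
157,fifth_distal_phalange,6,fifth_distal_phalange_6
158,fifth_distal_phalange,7,fifth_distal_phalange_7
159,fifth_distal_phalange,8,fifth_distal_phalange_8
160,fifth_distal_phalange,9,fifth_distal_phalange_9
161,fifth_distal_phalange,10,fifth_distal_phalange_10
162,fifth_distal_phalange,11,fifth_distal_phalange_11
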