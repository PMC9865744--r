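index,name,generic_number,region
1,ALA29,,N-terminus
2,ALA30,,N-terminus
3,VAL31,1.30,H1
4,TRP32,1.31,H1
5,VAL33,1.32,H1
6,VAL34,1.33,H1
7,GLY35,1.34,H1
8,MET36,1.35,H1
9,GLY37,1.36,H1
10,ILE38,1.37,H1
11,VAL39,1.38,H1
12,MET40,1.39,H1
13,SER41,1.40,H1
14,LEU42,1.41,H1
15,ILE43,1.42,H1
16,VAL44,1.43,H1
17,LEU45,1.44,H1
18,ALA46,1.45,H1
19,ILE47,1.46,H1
20,VAL48,1.47,H1
21,PHE49,1.48,H1
22,GLY50,1.49,H1
23,ASN51,1.50,H1
24,VAL52,1.51,H1
25,LEU53,1.52,H1
26,ALA54,1.53,H1
27,ALA55,1.54,H1
28,ALA56,1.55,H1
29,ALA57,1.56,H1
30,ALA58,1.57,H1
31,ALA59,1.58,H1
32,ALA60,1.59,H1
33,ALA61,,ICL1
34,GLU62,,ICL1
35,ALA63,,ICL1
36,LEU64,,ICL1
37,GLN65,,ICL1
38,THR66,,ICL1
39,VAL67,2.38,H2
40,ALA68,2.39,H2
41,ASN69,2.40,H2
42,TYR70,2.41,H2
43,ALA71,2.42,H2
44,ALA72,2.43,H2
45,ALA73,2.44,H2
46,ALA74,2.45,H2
47,ALA75,2.46,H2
48,ALA76,2.47,H2
49,ALA77,2.48,H2
50,ALA78,2.49,H2
51,ALA79,2.50,H2
52,ALA80,2.51,H2
53,VAL81,2.52,H2
54,MET82,2.53,H2
55,GLY83,2.54,H2
56,ALA84,2.55,H2
57,ALA85,2.56,H2
58,ALA86,2.57,H2
59,VAL87,2.58,H2
60,PRO88,2.59,H2
61,ALA89,2.60,H2
62,ALA90,2.61,H2
63,ALA91,2.62,H2
64,ALA92,2.63,H2
65,ALA93,2.64,H2
66,ILE94,2.65,H2
67,LEU95,2.66,H2
68,MET96,2.67,H2
69,LYS97,,ECL1
70,ALA98,,ECL1
71,TRP99,,ECL1
72,THR100,,ECL1
73,PHE101,,ECL1
74,GLY102,,ECL1
75,ALA103,3.22,H3
76,ALA104,3.23,H3
77,ALA105,3.24,H3
78,ALA106,3.25,H3
79,ALA107,3.26,H3
80,ALA108,3.27,H3
81,ALA109,3.28,H3
82,ALA110,3.29,H3
83,ALA111,3.30,H3
84,ALA112,3.31,H3
85,ALA113,3.32,H3
86,ALA114,3.33,H3
87,ALA115,3.34,H3
88,ALA116,3.35,H3
89,ALA117,3.36,H3
90,ALA118,3.37,H3
91,ALA119,3.38,H3
92,ALA120,3.39,H3
93,ALA121,3.40,H3
94,ALA122,3.41,H3
95,ALA123,3.42,H3
96,ALA124,3.43,H3
97,ALA125,3.44,H3
98,ALA126,3.45,H3
99,ALA127,3.46,H3
100,ALA128,3.47,H3
101,ALA129,3.48,H3
102,ALA130,3.49,H3
103,ARG131,3.50,H3
104,ALA132,3.51,H3
105,ALA133,3.52,H3
106,ALA134,3.53,H3
107,ALA135,3.54,H3
108,ALA136,3.55,H3
109,SER137,,ICL2
110,ALA138,,ICL2
111,ALA139,,ICL2
112,LYS140,,ICL2
113,TYR141,,ICL2
114,GLN142,,ICL2
115,ALA143,,ICL2
116,ALA144,,ICL2
117,ALA145,,ICL2
118,ALA146,,ICL2
119,ALA147,4.39,H4
120,ASN148,4.40,H4
121,LYS149,4.41,H4
122,ALA150,4.42,H4
123,ARG151,4.43,H4
124,ALA152,4.44,H4
125,ALA153,4.45,H4
126,ALA154,4.46,H4
127,ALA155,4.47,H4
128,MET156,4.48,H4
129,ALA157,4.49,H4
130,ALA158,4.50,H4
131,ALA159,4.51,H4
132,ALA160,4.52,H4
133,ALA161,4.53,H4
134,ALA162,4.54,H4
135,ALA163,4.55,H4
136,ALA164,4.56,H4
137,ALA165,4.57,H4
138,ALA166,4.58,H4
139,ALA167,4.59,H4
140,ALA168,4.60,H4
141,ALA169,4.61,H4
142,ALA170,4.62,H4
143,ALA171,,ECL2
144,ALA172,,ECL2
145,ALA173,,ECL2
146,ALA174,,ECL2
147,ALA175,,ECL2
148,ALA176,,ECL2
149,ALA177,,ECL2
150,HIS178,,ECL2
151,GLN179,,ECL2
152,ALA180,,ECL2
153,ALA181,,ECL2
154,ALA182,,ECL2
155,ALA183,,ECL2
156,ALA184,,ECL2
157,ALA185,,ECL2
158,ALA186,,ECL2
159,ALA187,,ECL2
160,ALA188,,ECL2
161,ALA189,,ECL2
162,ALA190,,ECL2
163,ALA191,,ECL2
164,ALA192,,ECL2
165,ALA193,,ECL2
166,ALA194,,ECL2
167,THR195,,ECL2
168,ALA196,,ECL2
169,ALA197,5.36,H5
170,ALA198,5.37,H5
171,ALA199,5.38,H5
172,ALA200,5.39,H5
173,ALA201,5.40,H5
174,ALA202,5.41,H5
175,ALA203,5.42,H5
176,ALA204,5.43,H5
177,ALA205,5.44,H5
178,ALA206,5.45,H5
179,ALA207,5.46,H5
180,ALA208,5.47,H5
181,ALA209,5.48,H5
182,ALA210,5.49,H5
183,ALA211,5.50,H5
184,ALA212,5.51,H5
185,ALA213,5.52,H5
186,ALA214,5.53,H5
187,ALA215,5.54,H5
188,ALA216,5.55,H5
189,ALA217,5.56,H5
190,ALA218,5.57,H5
191,ALA219,5.58,H5
192,ALA220,5.59,H5
193,ALA221,5.60,H5
194,ALA222,5.61,H5
195,ALA223,5.62,H5
196,ALA224,5.63,H5
197,ALA225,5.64,H5
198,ALA226,5.65,H5
199,ALA227,5.66,H5
200,ALA228,5.67,H5
201,ALA229,5.68,H5
202,ALA230,,ICL3
203,ALA231,,ICL3
204,ALA232,,ICL3
205,ALA233,,ICL3
206,ALA234,,ICL3
207,ALA235,,ICL3
208,ALA236,,ICL3
209,ALA237,,ICL3
210,ALA238,,ICL3
211,ALA239,,ICL3
212,ALA240,,ICL3
213,ALA241,,ICL3
214,ALA242,,ICL3
215,ALA243,,ICL3
216,ALA244,,ICL3
217,ALA245,,ICL3
218,ALA246,,ICL3
219,ALA247,,ICL3
220,ALA248,,ICL3
221,ALA249,,ICL3
222,ALA250,,ICL3
223,ALA251,,ICL3
224,ALA252,,ICL3
225,ALA253,,ICL3
226,ALA254,,ICL3
227,ALA255,,ICL3
228,ALA256,,ICL3
229,ALA257,,ICL3
230,ALA258,,ICL3
231,ALA259,,ICL3
232,ALA260,,ICL3
233,ALA261,,ICL3
234,ALA262,,ICL3
235,ALA263,,ICL3
236,ALA264,,ICL3
237,ALA265,,ICL3
238,ALA266,,ICL3
239,ALA267,6.29,H6
240,ALA268,6.30,H6
241,ALA269,6.31,H6
242,ALA270,6.32,H6
243,ALA271,6.33,H6
244,LEU272,6.34,H6
245,ALA273,6.35,H6
246,ALA274,6.36,H6
247,ALA275,6.37,H6
248,ALA276,6.38,H6
249,ALA277,6.39,H6
250,ALA278,6.40,H6
251,ALA279,6.41,H6
252,ALA280,6.42,H6
253,ALA281,6.43,H6
254,ALA282,6.44,H6
255,ALA283,6.45,H6
256,ALA284,6.46,H6
257,ALA285,6.47,H6
258,ALA286,6.48,H6
259,ALA287,6.49,H6
260,ALA288,6.50,H6
261,ALA289,6.51,H6
262,ALA290,6.52,H6
263,ALA291,6.53,H6
264,ALA292,6.54,H6
265,ALA293,6.55,H6
266,ALA294,6.56,H6
267,ALA295,6.57,H6
268,HIS296,6.58,H6
269,ALA297,6.59,H6
270,ALA298,6.60,H6
271,GLN299,,ECL3
272,ASP300,,ECL3
273,ASN301,,ECL3
274,ALA302,,ECL3
275,ALA303,,ECL3
276,ALA304,,ECL3
277,ALA305,7.31,H7
278,ALA306,7.32,H7
279,ALA307,7.33,H7
280,ALA308,7.34,H7
281,ALA309,7.35,H7
282,ALA310,,C-terminus
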