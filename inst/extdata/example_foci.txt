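// Reference=MNI

// Smith 2001: object identity working memory
// Subjects=14
-40	12	32
42	6	26
-44	-48	-14
-30	-54	44

// Jones 2003: object location working memory
// Subjects=10
-20	10	56
24	12	15
-18	-62	52
30	-70	38

// Lee 2005: spatial attention
// Subjects=18
-22	8	54
-26	-58	50
36	-66	42

// Chen 2007: shape recognition
// Subjects=12
-42	14	30
-38	-52	-16
-32	-50	46

// Weber 2009: verbal rehearsal
// Subjects=16
-46	14	8
-54	-40	4
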