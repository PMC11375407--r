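gene	note
PDCD1	starter list; replace with your curated checkpoint-gene set
CD274	starter list
PDCD1LG2	starter list
CTLA4	starter list
CD80	starter list
CD86	starter list
LAG3	starter list
HAVCR2	starter list
TIGIT	starter list
BTLA	starter list
VSIR	starter list
CD276	starter list
VTCN1	starter list
HHLA2	starter list
ICOS	starter list
ICOSLG	starter list
TNFRSF4	starter list
TNFSF4	starter list
TNFRSF9	starter list
TNFRSF18	starter list
CD27	starter list
CD70	starter list
CD40	starter list
CD40LG	starter list
CD28	starter list
CD47	starter list
SIRPA	starter list
IDO1	starter list
LGALS9	starter list
CD226	starter list
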