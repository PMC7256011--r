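position	guide_base	offtarget_base	penalty
1	A	C	0.4
1	A	G	0.6
1	A	T	0.8
1	C	A	0.6
1	C	G	0.2
1	C	T	0.4
1	G	A	0.2
1	G	C	0.4
1	G	T	0.8
1	T	A	0.6
1	T	C	0.8
1	T	G	0.2
2	A	C	0.6
2	A	G	0.8
2	A	T	0.2
2	C	A	0.8
2	C	G	0.4
2	C	T	0.6
2	G	A	0.4
2	G	C	0.6
2	G	T	0.2
2	T	A	0.8
2	T	C	0.2
2	T	G	0.4
3	A	C	0.8
3	A	G	0.2
3	A	T	0.4
3	C	A	0.2
3	C	G	0.6
3	C	T	0.8
3	G	A	0.6
3	G	C	0.8
3	G	T	0.4
3	T	A	0.2
3	T	C	0.4
3	T	G	0.6
4	A	C	0.2
4	A	G	0.4
4	A	T	0.6
4	C	A	0.4
4	C	G	0.8
4	C	T	0.2
4	G	A	0.8
4	G	C	0.2
4	G	T	0.6
4	T	A	0.4
4	T	C	0.6
4	T	G	0.8
5	A	C	0.4
5	A	G	0.6
5	A	T	0.8
5	C	A	0.6
5	C	G	0.2
5	C	T	0.4
5	G	A	0.2
5	G	C	0.4
5	G	T	0.8
5	T	A	0.6
5	T	C	0.8
5	T	G	0.2
6	A	C	0.6
6	A	G	0.8
6	A	T	0.2
6	C	A	0.8
6	C	G	0.4
6	C	T	0.6
6	G	A	0.4
6	G	C	0.6
6	G	T	0.2
6	T	A	0.8
6	T	C	0.2
6	T	G	0.4
7	A	C	0.8
7	A	G	0.2
7	A	T	0.4
7	C	A	0.2
7	C	G	0.6
7	C	T	0.8
7	G	A	0.6
7	G	C	0.8
7	G	T	0.4
7	T	A	0.2
7	T	C	0.4
7	T	G	0.6
8	A	C	0.2
8	A	G	0.4
8	A	T	0.6
8	C	A	0.4
8	C	G	0.8
8	C	T	0.2
8	G	A	0.8
8	G	C	0.2
8	G	T	0.6
8	T	A	0.4
8	T	C	0.6
8	T	G	0.8
9	A	C	0.4
9	A	G	0.6
9	A	T	0.8
9	C	A	0.6
9	C	G	0.2
9	C	T	0.4
9	G	A	0.2
9	G	C	0.4
9	G	T	0.8
9	T	A	0.6
9	T	C	0.8
9	T	G	0.2
10	A	C	0.6
10	A	G	0.8
10	A	T	0.2
10	C	A	0.8
10	C	G	0.4
10	C	T	0.6
10	G	A	0.4
10	G	C	0.6
10	G	T	0.2
10	T	A	0.8
10	T	C	0.2
10	T	G	0.4
11	A	C	0.8
11	A	G	0.2
11	A	T	0.4
11	C	A	0.2
11	C	G	0.6
11	C	T	0.8
11	G	A	0.6
11	G	C	0.8
11	G	T	0.4
11	T	A	0.2
11	T	C	0.4
11	T	G	0.6
12	A	C	0.2
12	A	G	0.4
12	A	T	0.6
12	C	A	0.4
12	C	G	0.8
12	C	T	0.2
12	G	A	0.8
12	G	C	0.2
12	G	T	0.6
12	T	A	0.4
12	T	C	0.6
12	T	G	0.8
13	A	C	0.4
13	A	G	0.6
13	A	T	0.8
13	C	A	0.6
13	C	G	0.2
13	C	T	0.4
13	G	A	0.2
13	G	C	0.4
13	G	T	0.8
13	T	A	0.6
13	T	C	0.8
13	T	G	0.2
14	A	C	0.6
14	A	G	0.8
14	A	T	0.2
14	C	A	0.8
14	C	G	0.4
14	C	T	0.6
14	G	A	0.4
14	G	C	0.6
14	G	T	0.2
14	T	A	0.8
14	T	C	0.2
14	T	G	0.4
15	A	C	0.8
15	A	G	0.2
15	A	T	0.4
15	C	A	0.2
15	C	G	0.6
15	C	T	0.8
15	G	A	0.6
15	G	C	0.8
15	G	T	0.4
15	T	A	0.2
15	T	C	0.4
15	T	G	0.6
16	A	C	0.2
16	A	G	0.4
16	A	T	0.6
16	C	A	0.4
16	C	G	0.8
16	C	T	0.2
16	G	A	0.8
16	G	C	0.2
16	G	T	0.6
16	T	A	0.4
16	T	C	0.6
16	T	G	0.8
17	A	C	0.4
17	A	G	0.6
17	A	T	0.8
17	C	A	0.6
17	C	G	0.2
17	C	T	0.4
17	G	A	0.2
17	G	C	0.4
17	G	T	0.8
17	T	A	0.6
17	T	C	0.8
17	T	G	0.2
18	A	C	0.6
18	A	G	0.8
18	A	T	0.2
18	C	A	0.8
18	C	G	0.4
18	C	T	0.6
18	G	A	0.4
18	G	C	0.6
18	G	T	0.2
18	T	A	0.8
18	T	C	0.2
18	T	G	0.4
19	A	C	0.8
19	A	G	0.2
19	A	T	0.4
19	C	A	0.2
19	C	G	0.6
19	C	T	0.8
19	G	A	0.6
19	G	C	0.8
19	G	T	0.4
19	T	A	0.2
19	T	C	0.4
19	T	G	0.6
20	A	C	0.2
20	A	G	0.4
20	A	T	0.6
20	C	A	0.4
20	C	G	0.8
20	C	T	0.2
20	G	A	0.8
20	G	C	0.2
20	G	T	0.6
20	T	A	0.4
20	T	C	0.6
20	T	G	0.8
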