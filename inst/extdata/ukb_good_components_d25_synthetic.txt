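# Synthetic stand-in for a 25-dimensional group-ICA "good components" list
# (21 non-artifactual component IDs out of 25).  Component 16 is the
# cerebellar component, conventionally excluded from cortical-surface
# analyses, leaving 20 usable maps.
1
2
3
4
5
6
7
8
9
10
11
12
13
14
15
16
17
18
21
22
23
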