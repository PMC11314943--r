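config_id,n_radars,S1,S2,S3,S4,S5,HL,HC,HR,densenet121,resnet50,efficientnet_b0,phresnet50,note
1,8,1,1,1,1,1,1,1,1,0.804,0.721,0.775,0.723,Baseline
2,7,1,1,1,1,1,1,1,0,0.703,0.774,0.688,0.738,Head radar removal
3,7,1,1,1,1,1,1,0,1,0.794,0.787,0.758,0.729,Head radar removal
4,7,1,1,1,1,1,0,1,1,0.771,0.771,0.662,0.728,Head radar removal
5,6,1,1,1,1,1,1,0,0,0.809,0.781,0.702,0.750,Retain single head radar
6,6,1,1,1,1,1,0,1,0,0.785,0.760,0.684,0.735,Retain single head radar
7,6,1,1,1,1,1,0,0,1,0.803,0.760,0.641,0.722,Retain single head radar
8,5,1,1,1,1,0,0,1,0,0.675,0.758,0.652,0.698,Side radar removal with central head radar retained
9,5,1,1,1,0,1,0,1,0,0.674,0.755,0.662,0.707,Side radar removal with central head radar retained
10,5,1,1,0,1,1,0,1,0,0.779,0.720,0.735,0.698,Side radar removal with central head radar retained
11,5,1,0,1,1,1,0,1,0,0.750,0.728,0.715,0.708,Side radar removal with central head radar retained
12,5,0,1,1,1,1,0,1,0,0.770,0.744,0.725,0.691,Side radar removal with central head radar retained
13,5,1,1,1,1,1,0,0,0,0.661,0.708,0.736,0.707,No head radar
14,4,0,1,0,1,0,1,0,1,0.592,0.721,0.698,0.662,2 head and side radars
15,4,1,0,1,0,1,0,1,0,0.612,0.712,0.709,0.687,3 side radars with central head radar retained
16,4,0,0,1,1,1,0,1,0,0.728,0.676,0.684,0.653,3 side radars with central head radar retained
17,4,0,1,1,1,0,0,1,0,0.735,0.724,0.696,0.669,3 side radars with central head radar retained
18,4,1,1,1,0,0,0,1,0,0.753,0.722,0.725,0.690,3 side radars with central head radar retained
19,4,1,0,0,1,1,0,1,0,0.702,0.668,0.678,0.625,3 side radars with central head radar retained
20,4,1,1,0,0,1,0,1,0,0.748,0.707,0.709,0.691,3 side radars with central head radar retained
21,3,0,1,0,1,0,0,1,0,0.550,0.672,0.678,0.656,Settings of earlier dual/triple-radar studies
22,2,0,0,1,0,0,0,1,0,0.594,0.649,0.633,0.613,Minimal pair: central side + central head
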