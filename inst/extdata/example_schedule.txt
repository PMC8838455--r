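flip_angle_deg te_ms tr_ms
34 21 3530
35.5294117647059 22.7794117647059 3619.41176470588
37.0588235294118 24.5588235294118 3708.82352941176
38.5882352941176 26.3382352941176 3798.23529411765
40.1176470588235 28.1176470588235 3887.64705882353
41.6470588235294 29.8970588235294 3977.05882352941
43.1764705882353 31.6764705882353 4066.47058823529
44.7058823529412 33.4558823529412 4155.88235294118
46.2352941176471 35.2352941176471 4245.29411764706
47.7647058823529 37.0147058823529 4334.70588235294
49.2941176470588 38.7941176470588 4424.11764705882
50.8235294117647 40.5735294117647 4513.52941176471
52.3529411764706 42.3529411764706 4602.94117647059
53.8823529411765 44.1323529411765 4692.35294117647
55.4117647058823 45.9117647058823 4781.76470588235
56.9411764705882 47.6911764705882 4871.17647058824
58.4705882352941 49.4705882352941 4960.58823529412
60 51.25 5050
61.5294117647059 53.0294117647059 5139.41176470588
63.0588235294118 54.8088235294118 5228.82352941176
64.5882352941177 56.5882352941176 5318.23529411765
66.1176470588235 58.3676470588235 5407.64705882353
67.6470588235294 60.1470588235294 5497.05882352941
69.1764705882353 61.9264705882353 5586.47058823529
70.7058823529412 63.7058823529412 5675.88235294118
72.2352941176471 65.4852941176471 5765.29411764706
73.7647058823529 67.2647058823529 5854.70588235294
75.2941176470588 69.0441176470588 5944.11764705882
76.8235294117647 70.8235294117647 6033.52941176471
78.3529411764706 72.6029411764706 6122.94117647059
79.8823529411765 74.3823529411765 6212.35294117647
81.4117647058823 76.1617647058823 6301.76470588235
82.9411764705882 77.9411764705882 6391.17647058824
84.4705882352941 79.7205882352941 6480.58823529412
86 81.5 6570
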