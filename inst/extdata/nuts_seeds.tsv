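name	omega3_pct_fat	fat_pct	omega3_g_per_g	preparation
Flaxseed	54.0	40.3	0.22	roasted
Chia seed	63.0	31.8	0.20	raw
Awkeotsang	62.8	12.5	0.08	raw
Walnut	10.5	67.9	0.07	raw
Pistachio	0.4	52.7	< 0.01	roasted
White sesame	0.3	58.7	< 0.01	roasted
Black sesame	0.3	54.4	< 0.01	roasted
Macadamia nut	0.2	71.6	< 0.01	roasted
Pumpkin seed	0.3	47.9	< 0.01	roasted
Sunflower seed	0.2	51.9	< 0.01	roasted
Hazelnut	0.1	66.5	< 0.01	roasted
Cashew nut	0.2	43.7	< 0.01	roasted
Watermelon seed	0.2	37.7	< 0.01	roasted
Lotus nut	11.4	0.5	< 0.01	raw
Peanut	0.1	43.9	< 0.01	roasted
Chestnut	6.2	0.8	< 0.01	roasted
Gingko nut	2.3	1.2	< 0.01	roasted
Almond	< 0.05	49.8	< 0.01	roasted
Pine nut	0.2	69	< 0.01	roasted
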