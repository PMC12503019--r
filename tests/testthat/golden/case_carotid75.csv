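time,position,pressure_Pa,flow_m3s
0,proximal,12334.50646,5.167701933e-6
0.0171875,proximal,12334.24821,5.235160742e-6
0.034375,proximal,12397.42442,5.410099171e-6
0.0515625,proximal,12542.16561,5.704115309e-6
0.06875,proximal,12756.66989,6.094665627e-6
0.0859375,proximal,13015.35129,6.549437173e-6
0.103125,proximal,13302.1673,7.043173962e-6
0.1203125,proximal,13614.33108,7.552522071e-6
0.1375,proximal,13947.83913,8.046375389e-6
0.1546875,proximal,14287.95757,8.490088884e-6
0.171875,proximal,14615.60198,8.856718317e-6
0.1890625,proximal,14916.84523,9.128634205e-6
0.20625,proximal,15182.25952,9.290618188e-6
0.2234375,proximal,15401.31117,9.329091154e-6
0.240625,proximal,15563.41214,9.239999005e-6
0.2578125,proximal,15663.85819,9.032194477e-6
0.275,proximal,15704.25967,8.720577632e-6
0.2921875,proximal,15687.19491,8.320603809e-6
0.309375,proximal,15615.09543,7.852978042e-6
0.3265625,proximal,15495.58941,7.348700493e-6
0.34375,proximal,15343.19709,6.842383713e-6
0.3609375,proximal,15172.64619,6.361619768e-6
0.378125,proximal,14994.19617,5.929015014e-6
0.3953125,proximal,14819.47918,5.573139921e-6
0.4125,proximal,14667.46687,5.325547351e-6
0.4296875,proximal,14555.10906,5.197301163e-6
0.446875,proximal,14478.95627,5.161150531e-6
0.4640625,proximal,14412.47418,5.165813098e-6
0.48125,proximal,14328.15195,5.171250479e-6
0.4984375,proximal,14221.55328,5.168074481e-6
0.515625,proximal,14110.25934,5.165096401e-6
0.5328125,proximal,14011.33759,5.167017247e-6
0.55,proximal,13925.49511,5.169224155e-6
0.5671875,proximal,13843.33081,5.168029256e-6
0.584375,proximal,13759.9536,5.166186101e-6
0.6015625,proximal,13678.3206,5.166905624e-6
0.61875,proximal,13601.58913,5.16853079e-6
0.6359375,proximal,13528.56639,5.168156699e-6
0.653125,proximal,13457.29538,5.166685083e-6
0.6703125,proximal,13388.55196,5.166786891e-6
0.6875,proximal,13323.66665,5.168136904e-6
0.7046875,proximal,13261.67345,5.168264435e-6
0.721875,proximal,13200.97557,5.167019697e-6
0.7390625,proximal,13142.12138,5.166687645e-6
0.75625,proximal,13086.61053,5.167834578e-6
0.7734375,proximal,13034.01914,5.168358759e-6
0.790625,proximal,12982.63653,5.167308165e-6
0.8078125,proximal,12932.40628,5.166594219e-6
0.825,proximal,12884.87005,5.167544957e-6
0.8421875,proximal,12840.21763,5.168456157e-6
0.859375,proximal,12796.76456,5.167613871e-6
0.8765625,proximal,12753.87574,5.166486037e-6
0.89375,proximal,12713.08549,5.167205103e-6
0.9109375,proximal,12675.22291,5.168586242e-6
0.928125,proximal,12638.63054,5.168013633e-6
0.9453125,proximal,12601.96159,5.166313045e-6
0.9625,proximal,12566.74702,5.16670356e-6
0.9796875,proximal,12534.71966,5.168848092e-6
0.996875,proximal,12504.23198,5.168692701e-6
1.0140625,proximal,12472.73387,5.165842693e-6
1.03125,proximal,12441.82234,5.165699641e-6
1.0484375,proximal,12415.11526,5.169923187e-6
1.065625,proximal,12390.6357,5.170250307e-6
1.0828125,proximal,12362.18501,5.162247026e-6
0,distal,11545.30594,5.238907206e-6
0.0171875,distal,11520.70034,5.23328024e-6
0.034375,distal,11506.87217,5.263059356e-6
0.0515625,distal,11521.95352,5.378203083e-6
0.06875,distal,11582.56366,5.607520896e-6
0.0859375,distal,11695.05316,5.937520882e-6
0.103125,distal,11855.76958,6.32784983e-6
0.1203125,distal,12057.97204,6.742544496e-6
0.1375,distal,12296.29635,7.1621467e-6
0.1546875,distal,12564.93661,7.571410294e-6
0.171875,distal,12854.42741,7.947214709e-6
0.1890625,distal,13152.23665,8.263217401e-6
0.20625,distal,13445.76714,8.500495898e-6
0.2234375,distal,13723.50389,8.648370061e-6
0.240625,distal,13974.14107,8.698658619e-6
0.2578125,distal,14186.8783,8.646053575e-6
0.275,distal,14353.48623,8.494116941e-6
0.2921875,distal,14469.32124,8.255651032e-6
0.309375,distal,14532.2152,7.946150753e-6
0.3265625,distal,14541.83354,7.581328106e-6
0.34375,distal,14501.08789,7.182202193e-6
0.3609375,distal,14417.11223,6.7767500700000004e-06
0.378125,distal,14299.46199,6.391853449e-6
0.3953125,distal,14157.88445,6.046872318e-6
0.4125,distal,14003.17112,5.759588966e-6
0.4296875,distal,13849.13655,5.55335178e-6
0.446875,distal,13710.02236,5.446241258e-6
0.4640625,distal,13593.00834,5.427873784e-6
0.48125,distal,13493.65225,5.454069008e-6
0.4984375,distal,13400.73618,5.47420595e-6
0.515625,distal,13306.36239,5.466039891e-6
0.5328125,distal,13210.92406,5.441633211e-6
0.55,distal,13119.05504,5.422151812e-6
0.5671875,distal,13033.08305,5.413732503e-6
0.584375,distal,12951.59173,5.408412303e-6
0.6015625,distal,12872.6987,5.399705164e-6
0.61875,distal,12796.35094,5.389282517e-6
0.6359375,distal,12723.24591,5.380484772e-6
0.653125,distal,12653.2399,5.372691549e-6
0.6703125,distal,12585.73774,5.364107573e-6
0.6875,distal,12520.75297,5.355569487e-6
0.7046875,distal,12458.637,5.34863887e-6
0.721875,distal,12399.18189,5.342453715e-6
0.7390625,distal,12341.80806,5.335278112e-6
0.75625,distal,12286.44296,5.327659877e-6
0.7734375,distal,12233.47579,5.321400534e-6
0.790625,distal,12182.89187,5.316293393e-6
0.8078125,distal,12134.15328,5.310518484e-6
0.825,distal,12087.02767,5.303928295e-6
0.8421875,distal,12041.86644,5.298293451e-6
0.859375,distal,11998.82584,5.294057104e-6
0.8765625,distal,11957.43446,5.289460486e-6
0.89375,distal,11917.31499,5.283719176e-6
0.9109375,distal,11878.77632,5.278550988e-6
0.928125,distal,11842.15709,5.275090055e-6
0.9453125,distal,11807.05408,5.271627645e-6
0.9625,distal,11772.89842,5.266576247e-6
0.9796875,distal,11739.94256,5.2616088e-6
0.996875,distal,11708.7896,5.258868768e-6
1.0140625,distal,11679.12312,5.25667848e-6
1.03125,distal,11650.02643,5.25206478e-6
1.0484375,distal,11621.67273,5.246749772e-6
1.065625,distal,11595.24991,5.245065249e-6
1.0828125,distal,11570.49966,5.244898081e-6
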