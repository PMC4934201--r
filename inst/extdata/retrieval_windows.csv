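algorithm,band,set,candidate,lambda_in,lambda_left,lambda_right,degree_r,degree_f
FLD,O2A,candidate,1,760.519,757.282,,,
FLD,O2A,candidate,2,760.519,755.121,,,
FLD,O2A,candidate,3,760.519,753.319,,,
3FLD,O2A,candidate,1,760.519,756.201,765.189,,
3FLD,O2A,candidate,2,760.519,751.877,769.135,,
3FLD,O2A,candidate,3,760.519,750.072,771.284,,
SFM,O2A,candidate,1,760.519,756.201,771.284,1,1
SFM,O2A,candidate,2,760.519,754.040,773.074,1,1
SFM,O2A,candidate,3,760.519,752.237,775.220,1,1
FLD,O2B,candidate,1,687.276,684.321,,,
FLD,O2B,candidate,2,687.276,682.102,,,
FLD,O2B,candidate,3,687.276,680.251,,,
3FLD,O2B,candidate,1,687.276,684.321,690.229,,
3FLD,O2B,candidate,2,687.276,682.442,692.441,,
3FLD,O2B,candidate,3,687.276,680.251,694.652,,
SFM,O2B,candidate,1,687.276,685.060,690.229,2,1
SFM,O2B,candidate,2,687.276,681.362,694.283,2,1
SFM,O2B,candidate,3,687.276,679.141,696.124,2,1
FLD,O2A,selected,1,760.519,759.081,,,
3FLD,O2A,selected,1,760.519,754.040,767.342,,
SFM,O2A,selected,1,760.519,758.721,768.776,1,1
FLD,O2B,selected,1,687.276,686.538,,,
3FLD,O2B,selected,1,687.276,686.538,688.015,,
SFM,O2B,selected,1,687.276,683.581,691.704,2,1
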