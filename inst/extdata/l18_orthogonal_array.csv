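# L18(2^1 x 3^7) orthogonal-array hyperparameter study: level indices per
# factor and the test accuracy [%] measured for each parameter set.
set,activation,overlap_ratio,layers,optimizer,hidden_units,learning_rate,dropout,batch_size,test_accuracy
1,1,1,1,1,1,1,1,1,76.36
2,1,1,2,2,2,2,2,2,75.76
3,1,1,3,3,3,3,3,3,76.43
4,1,2,1,1,2,2,3,3,74.29
5,1,2,2,2,3,3,1,1,71.10
6,1,2,3,3,1,1,2,2,73.49
7,1,3,1,2,1,3,2,3,78.01
8,1,3,2,3,2,1,3,1,74.55
9,1,3,3,1,3,2,1,2,74.15
10,2,1,1,3,3,2,2,1,81.08
11,2,1,2,1,1,3,3,2,78.35
12,2,1,3,2,2,1,1,3,79.95
13,2,2,1,2,3,1,3,2,80.13
14,2,2,2,3,1,2,1,3,80.33
15,2,2,3,1,2,3,2,1,82.66
16,2,3,1,3,2,3,1,2,78.07
17,2,3,2,1,3,1,2,3,79.53
18,2,3,3,2,1,2,3,1,75.28
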