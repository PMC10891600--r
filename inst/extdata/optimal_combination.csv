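# Reference optimal design parameter combination from the level-average
# analysis of the orthogonal-array study.
activation,overlap_ratio,layers,optimizer,hidden_units,learning_rate,dropout,batch_size
LeakyReLU,30,1,Adam,64,0.003,0.5,7000
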