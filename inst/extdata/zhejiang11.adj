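# Adjacency of the 11 prefecture-level cities of Zhejiang Province,
# read off the public administrative map. Binary (0/1) weights; one edge
# per line. Zhoushan is an island prefecture with a single neighbor.
Hangzhou Huzhou
Hangzhou Jiaxing
Hangzhou Shaoxing
Hangzhou Jinhua
Hangzhou Quzhou
Huzhou Jiaxing
Ningbo Shaoxing
Ningbo Taizhou
Ningbo Zhoushan
Shaoxing Jinhua
Shaoxing Taizhou
Jinhua Quzhou
Jinhua Lishui
Jinhua Taizhou
Quzhou Lishui
Taizhou Lishui
Wenzhou Lishui
Wenzhou Taizhou
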