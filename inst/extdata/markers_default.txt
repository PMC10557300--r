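# expectation-adverb markers, one per line
あるといい
いい
やっぱり
やっぱ
やはり
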