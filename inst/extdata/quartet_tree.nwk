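((human:0.2,orangutan:0.25):0.4,cynomolgus:0.075,rhesus:0.075);
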