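>IGHJ4*01 chain=heavy synthetic
WGQGTLVTVSS
>IGHJ6*01 chain=heavy synthetic
WGQGTTVTVSS
>IGHJ2*01 chain=heavy synthetic
WGRGTLVTVSS
>IGKJ1*01 chain=light synthetic
FGQGTKVEIK
>IGKJ2*01 chain=light synthetic
FGQGTKLEIK
>IGKJ4*01 chain=light synthetic
FGGGTKVEIK
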