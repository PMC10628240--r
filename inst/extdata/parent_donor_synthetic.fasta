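>parent-VH-synthetic chain=heavy murine donor stand-in
EVQLVESGGGLVQPGGSLRLSCAASGFTFSDYYIHWVKQRPGKGLEWVSAISGSGGSTYYADFSVKATLSADNSKNTAYLQMRLRNSLRAEDTAVYGARGYWGFDWGQGTLVTVSS
>parent-VL-synthetic chain=light murine donor stand-in
DIVMTQSPSSLSASVGDRVTITCRASQSISSYLNWYQQKPGKAPKLLIYAASSRQSGVPDRFTGSGSGTDFTLTISSLQPEDFATYYCQQWSSNPLTFGQGTKVEIK
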