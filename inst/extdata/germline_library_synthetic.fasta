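>IGHV1-46*01 chain=heavy synthetic template-derived stand-in
EVQLVESGGGLVQPGGSLRLSCAASGFTFSSYAMSWVRQAPGKGLEWMSAISGSGGSTYYADSVKRVTISRDNSKNTLYLQMSLRNSLRAEDTAVYRDYGSSYFDWGQGTLVTVSS
>IGHV1-2*02 chain=heavy synthetic template-derived stand-in
EVQLVESGGGMVQPGASLRLSCAVSGFTFSSYAMSWVRQTPGKGLEWASAISGSGGSTYYADSVKRVTFSDDNSANTLYLQMNSVRAEDTAVYYDYGSSYFDWGQGTLVTVSS
>IGHV1-69*01 chain=heavy synthetic template-derived stand-in
EVQLQESGGGLVQPGGSVRLSCAASGFTLSSYAMSWVRQAPGRGLEWISAISGSGGSTYYADSVKRVTISRDNSKNTTYFQMNSLRTEDTAVYSDYGSSYFDWGQGTLVTVSS
>IGHV3-23*01 chain=heavy synthetic template-derived stand-in
EVQLVESGGGLVKPGGSLRLTCAGSGFTFSSYAMSWVRQAPGKGLKWLSAISGSGGSTYYADSVKRVTISEDESKNTLYLQMNSLRAEDNAVYTDYGSSYFDWGQGTLVTVSS
>IGHV4-59*01 chain=heavy synthetic template-derived stand-in
EVQLVETGGGLKQPGGSLRLSCAASGFTISSYAMSWIRQAPGKGLEWGSAISGSGGSTYYADSVKRVTVSRDNSKDTSYLQMNSLRAEDTATYYDYGSSYFDWGQGTLVTVSS
>IGKV1-5*01 chain=light synthetic template-derived stand-in
DIQMTQSPSSLSASVGDRVTITCRASQSISSYLNWYQQKPGKAPKLLIYAASSLQSGVPSRFSGSGSGTEFTLTISSLQPEDFATYYCQQSYSTPLTFGQGTKVEIK
>IGKV1-39*01 chain=light synthetic template-derived stand-in
DIQMTQTPSSLPASVGDRVTITCRASQSISSYLNWYQQKPGSAPKLLIYAASSLQSGVPARFSASGSGTDFTLSISSLQPEDFATYYCQQSYSTPLTFGQGTKVEIK
>IGKV3-20*01 chain=light synthetic template-derived stand-in
DIQMTQSPASLSASLGDRVTITCRASQSISSYLNWYQQKPGKAPQLLIYAASSLQSGVPSRFSGSRSGTDYTLTISSLQDEDFATYYCQQSYSTPLTFGQGTKVEIK
>IGKV1-33*01 chain=light synthetic template-derived stand-in
DIQMTQSPSTLSASVGDKVTITCRASQSISSYLNWYLQKPGKAPKLLIYAASSLQSGVPSRLSGSGSGTDVTLTISSVQPEDFATYYCQQSYSTPLTFGQGTKVEIK
>IGKV2-28*01 chain=light synthetic template-derived stand-in
DIQMTQSPSSLSTSVGDRVTINCRASQSISSYLNWYQQKPGKPPKLLIYAASSLQSGVPSRFSSSYSGTDFTLTISSLQPEDLATYYCQQSYSTPLTFGQGTKVEIK
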