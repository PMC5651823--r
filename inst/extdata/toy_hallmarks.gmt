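TOY_INFLAMMATORY	synthetic example set	g00012	g00034	g00101	g00150	g00203	g00322	g00410	g00555
TOY_PROLIFERATION	synthetic example set	g00007	g00071	g00140	g00260	g00333	g00388	g00489	g00612	g00700
TOY_METABOLISM	synthetic example set	g00020	g00055	g00180	g00290	g00361	g00444	g00502
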