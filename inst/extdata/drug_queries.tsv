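label	pattern	roles
ide-cel	abecma	PS,SS
ide-cel	idecabtagene	PS,SS
ide-cel	ide-cel	PS,SS
ide-cel	bb2121	PS,SS
ide-cel	bb-2121	PS,SS
cilta-cel	carvykti	PS,SS
cilta-cel	ciltacabtagene	PS,SS
cilta-cel	cilta-cel	PS,SS
cilta-cel	jnj-68284528	PS,SS
cilta-cel	jnj-4528	PS,SS
cilta-cel	lcar-b38m	PS,SS
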