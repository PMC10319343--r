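STRESS_RESPONSE	stress response proteins	P0001	P0002	P0006
RIBOSOME	ribosomal proteins	P0003	P0004	P0005
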