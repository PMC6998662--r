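isomir_id	mirna_id
iso001	mir029
iso002	mir027
iso003	mir024
iso004	mir013
iso005	mir015
iso006	mir002
iso007	mir009
iso008	mir034
iso009	mir014
iso010	mir026
iso011	mir017
iso012	mir012
iso013	mir008
iso014	mir010
iso015	mir014
iso016	mir001
iso017	mir031
iso018	mir031
iso019	mir011
iso020	mir039
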