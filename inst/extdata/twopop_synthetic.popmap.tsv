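wild_01	wild
wild_02	wild
wild_03	wild
wild_04	wild
wild_05	wild
wild_06	wild
wild_07	wild
wild_08	wild
wild_09	wild
wild_10	wild
domestic_01	domestic
domestic_02	domestic
domestic_03	domestic
domestic_04	domestic
domestic_05	domestic
domestic_06	domestic
domestic_07	domestic
domestic_08	domestic
domestic_09	domestic
domestic_10	domestic
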