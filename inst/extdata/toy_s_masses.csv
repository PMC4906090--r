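# Region masses (kg) for the synthetic toy phantom.
region,mass_kg
liver,1.8
kidneys,0.3
heart,0.3
bladder_contents,0.2
bone,5.0
red_marrow,1.1
total_body,70
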