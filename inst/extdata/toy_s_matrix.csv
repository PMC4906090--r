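# Synthetic toy S-value matrix, mGy per MBq h. Not a published phantom:
# magnitudes are Lu-177-plausible (beta self-dose ~ mean energy / mass,
# photon cross-dose ~1e-4) and internally consistent with the mass table.
target,liver,kidneys,heart,bladder_contents,bone,red_marrow,total_body
liver,4.7e-2,1.1e-4,9.0e-5,2.0e-6,5.0e-5,7.0e-5,1.36e-3
kidneys,1.1e-4,2.9e-1,2.0e-5,5.0e-6,8.0e-5,9.0e-5,1.39e-3
heart_wall,9.0e-5,2.0e-5,2.7e-1,1.0e-6,4.0e-5,6.0e-5,1.31e-3
urinary_bladder_wall,2.0e-6,5.0e-6,1.0e-6,5.5e-1,2.0e-5,1.0e-5,1.72e-3
red_marrow,7.0e-5,9.0e-5,6.0e-5,1.0e-5,1.5e-3,6.0e-2,1.10e-3
osteogenic_cells,5.0e-5,8.0e-5,4.0e-5,2.0e-5,6.7e-2,1.2e-3,4.94e-3
total_body,1.2e-3,1.2e-3,1.2e-3,1.2e-3,1.2e-3,1.2e-3,1.21e-3
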