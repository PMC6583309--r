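journal,n_included
Annals of Internal Medicine,193
BMJ,648
JAMA,476
The Lancet,932
New England Journal of Medicine,876
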