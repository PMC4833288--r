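gene,allele,orf_name,orf_length,mutation
paqr-2,et36,F58B6.3b,552,D(GAT)282N(AAT)
paqr-2,et35,F58B6.3b,552,G(GGA)533R(AGA)
iglr-2,et34,ZC262.3b,773,W(TGG)83STOP(TAG)
iglr-2,et37,ZC262.3b,773,G(GGT)497D(GAT)
iglr-2,et38,ZC262.3b,773,Q(CAA)593STOP(TAA)
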