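>terL_synthetic terL
MHDITPKSLLSPCPSKIGCRNEVSPMFLTCRKRYLSPRVGRPFRIPGQPNTLLSYHLIFLAVSLFRNLARRHPRVHGIL
>integrase_synthetic integrase
MREVRWECVEKRGVVACGAFRTYAESLIDPFARPDHGLKGLTANPVSKALTPRVRYVVHRSSRALLATQAVSMRITRCY
>transposase_synthetic transposase
MHSALRCPKRTNLLINGTSHIIVECPRVMLVVDGVCNYAKTHSLFTPLRSCQSHLTALSMNMCINLAQATLGCPILLQH
>anti_repressor_synthetic anti_repressor
MTRRLNLAKRLRLLNSLRTCASAEVDVYRLCCGEEATCATGAIMLMHNNSPTLSLKDHQNRCHGCRARTSHNDPLSSGD
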