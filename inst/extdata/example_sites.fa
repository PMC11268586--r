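>LacI
AATTGTGAGCGGATAACAATT
>TetR
TCCCTATCAGTGATAGAGA
>AraC
TAGCATTTTTATCCATAAG
>LexA
CTGTATATATATACAG
>FNR
TTGATCTAGATCAA
>CRP
TGTGATCTAGATCACA
>ArcA
GTTAATTAAATGTTA
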