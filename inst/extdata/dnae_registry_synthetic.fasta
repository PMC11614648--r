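>SspDnaE_N family=DnaE synthetic stand-in sequence
CYTHRIWIGDPNKLEGRFFRVPMKKSKPNWNDRPFETMRFSWWPNPVMIHTMKMQNYDSN
QMSLMLERFSRPIHSVHPNNGYHFFRKQAMQCKPWYQTVMVYMMCLWYSGDNEMKEYTNK
TVQ
>SspDnaE_C family=DnaE synthetic stand-in sequence
LCCYWVRGPQWKCFADYTYQANMSPGDMRNVIHSVN
>NpuDnaE_N family=DnaE synthetic stand-in sequence
CGLDVYCGGVTKTGSCGSMPTIWCVQCHLQMCCAGWTLWLRPLREFFEISWEITDNSIGE
KMSTVWDKGNRSAQFTIGSVPDGGDDLETIAYGVDARIFIQS
>NpuDnaE_C family=DnaE synthetic stand-in sequence
MVVYMKTRHRIVFLVAPNTIKWLRVLESLLFIEWEN
>AvaDnaE_N family=DnaE synthetic stand-in sequence
CIQRTKMTSCAVQPHVVYCNEQLHTNGDNRVGWHQWWDDSTHVFMPTREAIKNNPQTHNH
SWVPRGRQWNVIYMDPFIKGSNEKRKLFHLGKSRGWDHHDDLA
>AvaDnaE_C family=DnaE synthetic stand-in sequence
MNKMWIKHCMAFSVQAAMWNVRHMHAWRFAGMAYDN
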