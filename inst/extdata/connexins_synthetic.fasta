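>Cx26_synthetic synthetic stand-in (real accession NP_032151 unavailable offline); 226 aa
CCICWYPRECAARCQCMSGFCVLYEYMDPDTYNPERWHINQHWASLMDEAWTVPWSFWAS
HLPFTLEQMEHQECFNGTHPCVGIGDSGVQISEMQDLWYSPYNRCMNNMTWYNEYWYNGT
NHTQKVREIWVSCNFQHMYFWFQDLETPDMLVYIYCRSYAQHCQRSFYQRSGFLHLVLMV
RCMVGPGQGHGSAFEYTVCGHNLRSRMQPFEEEVDWTMVIHWSDTA
>Cx30_synthetic synthetic stand-in (real accession AAH13811 unavailable offline); 261 aa
WDVHMLAVRNRLPFYCSAAGSVEFWVNQVFQMTWWDSWSWEDQYHFFADHAARRDIHFLC
TMHHLCSHPTMMCLDVSDMCDCCAARDWVGYIPWQSIGPMPWLRPDGYVHADGWTLGIDT
FCTQKVREISDAMNDCMWNIDMLVLFANFEGNYMIYYHERIRGTHWAPCEYEHNLSTTYW
DVAHARVHDPALLGINIMLGWQYVQMFYIWSAGVNCICHCIFNHIPRICHVQLAMTMYQI
NLYFYDSTDEACPFFDTSRSF
>Cx32_synthetic synthetic stand-in (real accession AAH26833 unavailable offline); 283 aa
FDMHLSMMRRFTRNFELDWEHRGWSWAEIVMTVLYNPNIQFALFYGPYSEGIQGYQEYNS
GYCTNHRWNTLLNIMHAQVIDHVMSTTFRHDQHQMNHWIWELHKLNGSFASYWYPQALSI
PWTQKVREIPFCTCMVLFMAGGTEEMRFRYEMPTDDPNDRINEPSQSHLCRTPPNYSDWP
DVNYQGFGRHVEEAQQNADQHYASWDRYMEQFLMANQATISYPVRGNPDIMAISGVNAFW
WFPGTESRFMNMIGCYGCLLYDCMTVLGGFMLSFVTNRGYINT
>Cx31_synthetic synthetic stand-in (real accession NP_001153484 unavailable offline); 270 aa
CPPLPRQQPQIYMFQRSCDVTTRSTVRQYCRLHMDFNLQVLQYNQICHCNECYWCYCCCF
AYAQMNCHWCRSVILRIPWNLNTQYMNYRLLTNDYETYAGYQLKEPLRQFVLYGCACVWQ
AQKHVFYVTWGVGDFPYHFIQFPLWCTYDPATQAIENWAMFYIVSGWMYQWSETDILEDT
EPVRDGAHHFAHVFAPCCIWHRACDMGGYPMNVAFSVRWMGECHPAASDQHMGAEDCRLM
SMSPFGFYREAPPFDSWHGSYQNEVMNFIP
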