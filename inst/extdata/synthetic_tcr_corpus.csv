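cdr3b
MKKQNYTYIEKAVP
KHDTNHTTPYHCDCNEKNRHFPI
HRHFEGNRCTLWMGKDGTLWLI
DSEVGEFSVCMMVIDIPHPWYRI
PSLSENQWQNSYFMCM
CIYWFGCLKTSAWPSQRH
TRRENITHKATTTGYIPQWLIP
SQIPPDWPQQPVWCNYN
TVMITACIVTTTY
EMKIYHFSTIDDMQT
RQICVITTSEMIIFPCLYR
DEEWNSLFNDSMWVVALNCLVISIAAFVCN
LYKSVMSSYREFFEWFGKQAEMQLWEK
LISRLMFPCISKFWRCNANKTFRNTEHRAY
SWILNERPQKAFPFEDCKKINQMP
HKKVHCLVVYAQG
PPMLWYTCHG
EFYSSCFMMMAQAHVQGKVTENA
MVMIRSTKYDAIVT
KCDYEMCEMMEC
ELDTKKLTCWMHGQLRWARNQIGEYPWQW
PEQNCHRPFFEFQFQKIRTVKKHSHDVPCQ
STGTGDSQYSRMEMRYMNSQCRIPLLDHV
SCTYAHADMTAAQYTCIKAIPGWG
FDVEPAWRPKWGWQLLDQH
GRRNNRCLKAMWLMQQKNPCDPD
ITWECATCAWPTIYPVNHWQAKIPDIL
TGFEIMKTDNEPQ
DHYKHGHSYNCKQCE
KLLPAEGSWK
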