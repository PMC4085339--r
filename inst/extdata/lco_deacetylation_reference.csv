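adduct,precursor_before,precursor_after,fragments_before,fragments_after,structure_before,structure_after
H,1162,1120,493;678;738;881;941;1102,493;696;899,"IV(C20:3, Cb, OAc)","IV(C20:3, Cb)"
Na,1184,1142,515;700;760;903;963;1124,515;718;921,"IV(C20:3, Cb, OAc)","IV(C20:3, Cb)"
Na,1186,1144,517;702;762;905;965;1126,517;720;923,"IV(C20:2, Cb, OAc)","IV(C20:2, Cb)"
Na,1188,1146,519;704;764;907;967;1128,519;722;925,"IV(C20:1, Cb, OAc)","IV(C20:1, Cb)"
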