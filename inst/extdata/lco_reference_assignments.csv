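sample,parent_mz,adduct,fragments,structure
wild_type,1114,Na,487;690;893,"IV(C18:3, Cb)"
wild_type,1118,Na,491;694;897,"IV(C18:1, Cb)"
wild_type,1120,Na,493;696;899,"IV(C18:0, Cb)"
wild_type,1134,H,465;710;913,"IV(C18:3, Cb, OAc)"
wild_type,1134,Na,507;710;913,"IV(C18:1-OH, Cb)"
wild_type,1134,Na,493;696;899,"IV(C18:0, Cb, CH3)"
wild_type,1136,Na,712;915,"IV(C18:0-OH, Cb)"
wild_type,1142,Na,515;718;921,"IV(C20:3, Cb)"
wild_type,1144,Na,517;720;923,"IV(C20:2, Cb)"
wild_type,1146,Na,519;722;925,"IV(C20:1, Cb)"
wild_type,1162,H,493;678;738;881;941;1102,"IV(C20:3, Cb, OAc)"
wild_type,1162,Na,493;678;738;881;941;1102,"IV(C18:0, Cb, OAc)"
wild_type,1162,Na,535;738;941,"IV(C20:1-OH, Cb)"
wild_type,1184,Na,515;700;760;903;963;1124,"IV(C20:3, Cb, OAc)"
wild_type,1186,Na,517;702;762;905;965;1126,"IV(C20:2, Cb, OAc)"
wild_type,1188,Na,519;704;764;907;967;1128,"IV(C20:1, Cb, OAc)"
wild_type,1190,Na,521;766;969,"IV(C20:0, Cb, OAc)"
noeT_mutant,1092,Na,465;668;871,"IV(C16:0, Cb)"
noeT_mutant,1096,H,469;672;875,"IV(C18:1, Cb)"
noeT_mutant,1098,H,471;674;877,"IV(C18:0, Cb)"
noeT_mutant,1114,Na,487;690;893,"IV(C18:3, Cb)"
noeT_mutant,1116,Na,489;692;895,"IV(C18:2, Cb)"
noeT_mutant,1118,Na,491;694;897,"IV(C18:1, Cb)"
noeT_mutant,1120,H,493;696;899,"IV(C20:3, Cb)"
noeT_mutant,1120,Na,493;696;899,"IV(C18:0, Cb)"
noeT_mutant,1122,H,495;698;901,"IV(C20:2, Cb)"
noeT_mutant,1142,Na,515;718;921,"IV(C20:3, Cb)"
noeT_mutant,1144,Na,517;720;923,"IV(C20:2, Cb)"
noeT_mutant,1146,Na,519;722;925,"IV(C20:1, Cb)"
noeT_mutant,1148,Na,521;724;927,"IV(C20:0, Cb)"
noeT_mutant,1160,Na,533;736;939,"IV(C20:2-OH, Cb)"
noeT_mutant,1162,Na,535;738;941,"IV(C20:1-OH, Cb)"
noeT_mutant,1164,Na,537;740;943,"IV(C20:0-OH, Cb)"
noeT_mutant,1172,Na,545;748;951,"IV(C22:2, Cb)"
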