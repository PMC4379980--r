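>Copia_GAG synthetic reference domain
WSEKKRFPVNIYTQHPSCGFKKGSMWFWLDAAPPFCGPPYKFNCICNYWTIKHDVGDAFWFAQWYEAVSFNFAFFRVRDSVRWLDDAMSILRSNIRAYEMKMMGSHARCAYQRREMLCHM
>Gypsy_GAG synthetic reference domain
WSEKKRFPVNIYTQHPMCGFKKGSNWFWLDAAPLTCGPPYKFNCICNYWTTMHDQGDAFDFAQWYEALSANFAFFRHRDSVRWLDDAHHILRENIRAMEMKMMGSHARCIYQRREMLCHM
>Copia_PR synthetic reference domain
VTSARKRCVGNCDHGASKVECHSTMSWGERMTYKESTQHSLHAYACCYSYGLMFRFVPMSFRERYTVFRILDCWDWKLKQKEIRPVTEGKIRKADSEHLM
>Gypsy_PR synthetic reference domain
VTSARKRCVGNCDHGASKVEVHTSMSWGEPMTYRESTQMSLHAYACCYSYGLMFRFGPMSFRIRYTVFRIWFCWDWKLKHAEIRPVTEYKIYKADMEHLM
>Copia_INT synthetic reference domain
MRFMLHENHQCWEVDDRRTCSMTEKYKFIQWGYRSSVNMLIQGHRMMITWGGMSWIFSDEDIVMMDFPYWLEDMAKLDHLQCAANVNGAKRLGHWHEWIQVQMVHEQAPAYWSHKFYKDWWICLLVNSLLMTYFITGLLCICPPGVFVGSATEMMECDNW
>Gypsy_INT synthetic reference domain
MRFMLHEFSQCWEVTSRRTCSMTEKYKFIGWGIRSSVIMLIQGHRFMITDGGMSWIFMDEDTVMMDFPEWLEDNAPLDHLPCAANVNGAKRLGHWHELIQVQMVHEQAPADWSQKFYKDWWLCLLVNSLTMTYFITGLLCICPPGVFRGSHTEMMFCDNW
>Copia_RT synthetic reference domain
QNYGAHAAQDTHASGRFYKKRFWVFSNVDFNMQGMQANGISARLRDNNIPHIGFVGPCEVVYYWQLVVSGDWEKEDPDRIGGFGDMAYATYICCYPLYAYVDDIKHWHWFWSLAGNAAYVSDEVLHPPWARAWARGGEEPMRYGMIPRRYTCMMFSQMEMAPNTREQCHGQQDPQMDHRDVRTNYLIAPHAQENTAPNVH
>Gypsy_RT synthetic reference domain
TNYGAHAYEDTHASGRFYKKRFWVFSNVDFNMQGMQANGMSAALRVNNIPHIGFVAPCEVVYYWQLVVSGDWEKEDPDRIGGTGDYAVATYICCYPLYAYVDDMKHWHWRWSLAGNAAQVSWEVIHPPSARAVARGAEEPMRDGMIPLRDTCMMFSQMYMAPNTREQCHGQQDPQMDHFDVRTNYLTAFHAQENTAPNPH
>Copia_RH synthetic reference domain
TVMVFPQQFRWNWIFIYHAGCCMTRTCHRQYCCVDCIPDQLVWFGELDNCELMGRMYTSGFAQEYYASRAKACATHECMSEMLNVRSHYMHCVFEFQDVAGFRYGINNFTMCAMPCDVIGRKEGAECIPQ
>Gypsy_RH synthetic reference domain
TVMVFPQQFRWNWIMIYGAGCCETRLCHRQYCCVDCTPDQLVWFGELDNCVLMGRMETSGFAQEYYASRAKACATHECNSWMLNIRSHYFHCVFEVQDVAGFHYFHNNFTMNWMPCDVIGRKEGAECIPQ
>Copia_CHD synthetic reference domain
SDAEKMLPDYRRKTPKWCVNRWIWNCHVRKWAMRQLILVYFCGMEAPQMDDWMYANYPRFEKYNVAIGGE
>Gypsy_CHD synthetic reference domain
MDAEKMLPDYRRKTPKWCVNRWIWNCHVRIWAMRQLQLVYFCGNWAPQHDDWMYHNYPRFEKYNWAIGAE
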