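>HOX1_m1 group=HOX1
MMALMVTRHEFQYVRDKEFPFYAIDALMRYEEVPFECVDTVGGCYDCGLIVATRRPLKNY
>HOX1_m2 group=HOX1
TFALEDTRHEFQQVRDKEFPFYCIDRLMRAGDPPNECVDTVGGCYDCGLIVATHEPLKNY
>HOX1_m3 group=HOX1
TTALEVARHEFQYGRNKEFPLYCIQALMRFEEMPFECVDTRGGCYDDGGIFATHAPLRTY
>HOX1_m4 group=HOX1
TFMLEVTRHEFQFVRCDEFPFYCCDALMRIEEVPFECVDTVRGCSDCGEGFATHEPLNNY
>HOX1_m5 group=HOX1
VFALMVTRHGQQYVRWKEFPFYCYDYLMLIEEVPFETVDCVGGCYDCGLIFFTIAPLKNY
>HOX1_m6 group=HOX1
LAALEVTRHEFIFVRDGEFRFYCIDALMRIEEVPFFCVLTVGGCYDCKTIFATHEPLKNY
>HOX2_m1 group=HOX2
NLQMCSMRPIWLPGAMPLPRWHIEGFYSWSWDHDLLHWPLQMPDLWCHYMMAILKNVVRA
>HOX2_m2 group=HOX2
NLQMCSQWTGWLCGAFPLLRTRIPDLYSNSWDWDLLWWPLQMPDWWSHYMAAGLINPVYA
>HOX2_m3 group=HOX2
NLPCCSQRELWLMGMMPRPRTRIEALYANSQDHDLLHWPLMMPDLWCHYMMLGLKNPYRA
>HOX2_m4 group=HOX2
NWQMCSQATGWLPGAMPGPRTCIERLYSNSWDHGALHWPLWMPDEWCSYMMAGLKNPVRA
>HOX2_m5 group=HOX2
NLGMESQRTGQLPGLMPPKRQRDEELYSDSWDHDLLHWPHQMPDAWCFYMEAGLKINVRA
>HOX2_m6 group=HOX2
NLQMCSQYTGWLPNVHPLPRTLIEGPYENSWDHELLAWPTQMPDLWCHYMFYGLVNPVRA
>HOX3_m1 group=HOX3
MAAADFHGSPAWVLQLCQKHCRIDCTDMFADQGSLIKDCGCSKFTNYESCDVGVPINYAL
>HOX3_m2 group=HOX3
MANVDFHGTPAWVLQLCSKTCRIDCTDMRADQGSLIKDYGCSKFFNYKYCDVTVTIHYAN
>HOX3_m3 group=HOX3
MAAHDFHGSLAWPLQLMSKTCRIDCTDLFEDQVSLIKDCGCSKFTNYEGCDVTWMIHYAW
>HOX3_m4 group=HOX3
MAAVDMHGSPAWVLQLCSKTCRIDCTSMYAPQGSLIKDCGCWWFMNYEGCLVTIMLHIAW
>HOX3_m5 group=HOX3
MAAVDFHGSPAWVLQLCSKTCRISCTDMFADGGALIKDCGQSKFKNQEGCPVTVMIHVAH
>HOX3_m6 group=HOX3
MAAHDFHGSPAWVLQRCSSTCRISCTDMNADLGSLYKDWGCSKFTNREGSDVTVMIHYAW
>HOX4_m1 group=HOX4
WAYDLSPVAKMFQDNMQSFIGEFNVHPLQEANDARYNRSTDATVDTEMHLYYDVMFSPRW
>HOX4_m2 group=HOX4
FPYDLSPVAKMFGDFMQSFIGEFNVHFLSECNPAAVYRAGTATLNTEMPLSHDVMDSPEW
>HOX4_m3 group=HOX4
WPYDLSPVAKMFNDFMQSNIFQFNVFPLSECNPARYYLSTTATSDTCMHLSHDVMFSPEP
>HOX4_m4 group=HOX4
WPYDLSPVQKMGQDFMQSFIEEFNVHPASQCKKAPYQRQTTATLDTEMHLSHDKMFSPEW
>HOX4_m5 group=HOX4
NPYDYSQVATMFQDFMQSFIGEFNVHPLSECNPARYFRSTTATLDTEMFLSYDVIFSPEN
>HOX4_m6 group=HOX4
CDYNGSPVAKMFQDFMQSLIGEDCVHPMSECNPPRYNRSTTANLDTEMHLSHDVLFSPEW
>HOX5_m1 group=HOX5
YETRNYNWGDNWTSQLIGRAHPFTNWGGWLRYNCCCEDPSWCFWLLPDSNEEEHDVEILL
>HOX5_m2 group=HOX5
YYTRNYNCGDNWNSQLIGRALPFTTQGGWLRTNCHCEIFSWCFWLFPDQCEEETAYEILL
>HOX5_m3 group=HOX5
YETRFYNCGDNTTSQLIGKAHPFTMWGGWDRTNCCCELFSWCFKLFPDSNNEETAVEILC
>HOX5_m4 group=HOX5
YETRNYNCGDNWTSQLIGRAHPFGTWHGKLRTNCCCEIFSWCHWLFHDSEEEATAVEILL
>HOX5_m5 group=HOX5
YRTRNYHDGDNWTSQLIGRTEPFTVWRGWLRPNCCCEYFFWCIWLFPDMNEEETAVEILK
>HOX5_m6 group=HOX5
YETRNYNCGQNWTSQLFERAHNFTTWGGWLRTNCFCEQFSMCFWLFPDSNEEETAQEILW
>HOX68ftz_m1 group=HOX6-8_ftz
LCIHTQSCDWHFHVLSCQYCDNYLDWGIAEAPCHRYFFWANQPPHYPQVRISFRWQVNVF
>HOX68ftz_m2 group=HOX6-8_ftz
WCIHHQDCDDLFWGLSTDQCDRQLDKGIAEAPCHRYFFYANQVEHYPRVVICFRWQVPVF
>HOX68ftz_m3 group=HOX6-8_ftz
LCIHTQDCDQVFWHQSTQYCDRQLLWGIQESGCHCYFFYANQPERYPRTRICWRWSVPVN
>HOX68ftz_m4 group=HOX6-8_ftz
LVIHTQDCDFVFLVLSTQKCDRQLDWQIAEAPCHRWFFYANQPEHYPRVRICKRWIWPVF
>HOX68ftz_m5 group=HOX6-8_ftz
LCIHTQDCDIVFWVQSTMSCDDQLDWGIAEAHCHRYFFYANQPEHSPMVRICFSAQWPVF
>HOX68ftz_m6 group=HOX6-8_ftz
LSIHTQDCDDVFWVLSTQYTDRQLDWGIAEAPCHRYFFYANQPEPYPPVRISFRWQVPVF
>HOX68Antp_m1 group=HOX6-8_Antp
LEWRPRMPKQITCVYFDNGMERPHYHQEMYMLSHRENFPPYYVAMTQDMMFLRSKEDAEI
>HOX68Antp_m2 group=HOX6-8_Antp
LEFRLTMPKQITHVQHDNGQERPHYHCVMYMLSSRENFPFYYMNFFQNMMFWYSKEDREM
>HOX68Antp_m3 group=HOX6-8_Antp
LEFRHRMCKQITGVYHDNGQGRPHYHCVMYMLWHRENFPIYYQALFRDMEFERSKEDQEM
>HOX68Antp_m4 group=HOX6-8_Antp
LEFRLRMPKQHTHVYHDNGQERPHYHCVMSMLSHRETFPFYIQALFQDMMFERSKEDAEK
>HOX68Antp_m5 group=HOX6-8_Antp
LEFRLRMPKNITHVYHDNGQELPHYHCVMYMLYDRENFPFYYQMLFQDMMFERSKLAAEM
>HOX68Antp_m6 group=HOX6-8_Antp
LEYRLKMPKQMTHHYHYWGQERPHYHCDMRMLSHREEFPFYYQTLFQDMMFQRSKRDAEM
>HOX68UbxAbdA_m1 group=HOX6-8_UbxAbdA
YTVMNCEETEELQKLMDKAIEMFDYFKRRSCDSSYKMLIYQIFSKKSSQDHIFEKTTFMW
>HOX68UbxAbdA_m2 group=HOX6-8_UbxAbdA
YTVMNCEWQECLWKLMFEAIEMFDYRIRQVPDSDYKMLIYQIDSKKSAQDHIFEKTTFMS
>HOX68UbxAbdA_m3 group=HOX6-8_UbxAbdA
YTVMNCCWTEELQKLMFKQISMFDYFIRQVPDSDYKMLIYQIDSKKMAQDWIFEKTTFMS
>HOX68UbxAbdA_m4 group=HOX6-8_UbxAbdA
HTVMICTWTEELQKLNFKAIEMFDYFIRQVPTSAYKMLIYQDDSKKSAHTHEFEKQTFMS
>HOX68UbxAbdA_m5 group=HOX6-8_UbxAbdA
YTVMNCWWLCPLYKLWFKAIEMFDYFIRMVYDSDYKMLIYQIDSKKSVFDHIFEKTTFGS
>HOX68UbxAbdA_m6 group=HOX6-8_UbxAbdA
YTVMNCEVTEELQKLMFKGIEMFEYFIRLVVDSDLKMLIYQIDSKKSAQDHIFYETTFHL
>HOX913_m1 group=HOX9-13
SRSTEMRIIFNGVKEELIKVPPWPGYWRSCIVPNNDVGHAHVFFKRGIWHMIRIKSTYFG
>HOX913_m2 group=HOX9-13
DREPQWRIIFNGPKEELIKVPRWPGYFRSFIVIYNVVGHAHVFFQRMIWHMIRIKSTYFG
>HOX913_m3 group=HOX9-13
IRKPQGRIIFNGMKEELIKVPRWPGYWRSWIVPYNVVGHRHVFFERCDWHMIRIKSTYFG
>HOX913_m4 group=HOX9-13
IREPQGRIIFNEPKEPEIKVPRHPGHWRSWIVNYNVVFHAHVFFQRCPWHMIRIKSTYFG
>HOX913_m5 group=HOX9-13
IREPFGRIIFNMPKEELIKVPDWPGYWRSWIVPYNVVGHAQVWFQRCIWTMIRIKSTYFP
>HOX913_m6 group=HOX9-13
IREPQGRIIFNGPKEETIDVPRWYGYMRSWRGPYNVVGAAHFFFQRCIWHRIYKKSTYFI
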