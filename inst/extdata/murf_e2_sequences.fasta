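>MuRF1_RM Rattus norvegicus MuRF1/TRIM63 residues 1-115 (RING + MFC)
MDYKSGLIPDGNAMENLEKQLICPICLEMFTKPVVILPCQHNLCRKCANDIFQAANPYWT
NRGGSVSMSGGRFRCPSCRHEVIMDRHGVYGLQRNLLVENIIDIYKQECSSRPLQ
>MuRF1_FL Rattus norvegicus MuRF1/TRIM63 full length (UniProt Q91Z63)
MDYKSGLIPDGNAMENLEKQLICPICLEMFTKPVVILPCQHNLCRKCANDIFQAANPYWT
NRGGSVSMSGGRFRCPSCRHEVIMDRHGVYGLQRNLLVENIIDIYKQECSSRPLQKGSHP
MCKEHEDEKINIYCLTCEVPTCSLCKVFGAHQACEVAPLQSIFQGQKTELSNCISMLVAG
NDRVQTIISQLEDSCRVTKENSHQVKEELSHKFDALYAILDEKKSELLQRITQEQEEKLD
FIEALILQYREQLEKSTKLVETAIQSLDEPGGATFLLSAKPLIKSIVEASKGCQLGKTEQ
GFENMDYFTLNLEHIAEALRAIDFGTDEEEEFTEEEEEEDQEEGVSTEGHQ
>UBE2E1 Mus musculus (UniProt P52482)
MSDDDSRASTSSSSSSSSNQQTEKEGSTPKKKESKVSMSKNSKLLSTSAKRIQKELADIT
LDPPPNCSAGPKGDNIYEWRSTILGPPGSVYEGGVFFLDITFTPEYPFKPPKVTFRTRIY
HCNINSQGVICLDILKDNWSPALTISKVLLSICSLLTDCNPADPLVGSIATQYMTNRAEH
DRMARQWTKRYAT
>UBE2J1 Mus musculus (UniProt Q9JJZ4)
METRYNLKSPAVKRLMKEAAELKDPTDHYHAQPLEDNLFEWHFTVRGPPDSDFDGGVYHG
RIVLPPEYPMKPPSIILLTANGRFEVGKKICLSISGHHPETWQPSWSIRTALLAIIGFMP
TKGEGAIGSLDYTPEERRALAKKSQDFCCEGCGSAMKDVLLPLKSGSGSSQADQEAKELA
RQISFKAEVNSSGKTIAESDLNQCFSLNDSQDDLPTTFQGATASTSYGAQNPSGAPLPQP
TQPAPKNTSMSPRQRRAQQQSQRRPSTSPDVLQGQPPRAHHTEHGGSAMLIIILTLALAA
LIFRRIYLANEYIFDFEL
>UBE2J2 Mus musculus (UniProt Q6P073)
MSNNSNKRAPTTATQRLKQDYLRIKKDPVPYICAEPLPSNILEWHYVVRGPEMTPYEGGY
YHGKLIFPREFPFKPPSIYMITPNGRFKCNTRLCLSITDFHPDTWNPAWSVSTILTGLLS
FMVEKGPTLGSIETSDFTKKQLAAQSLVFNLKDKVFCELFPEVVEEIKQKQKAQDELSNR
PQNLPLPDVVPDGELHRGQHGIQLLNGHAPAAGPNLAGLPQANRHHGLLGGALANLFVIV
GFAAFAYTVKYVLRSIAQE
>UBE2L3 Mus musculus (UniProt P68037)
MAASRRLMKELEEIRKCGMKNFRNIQVDEANLLTWQGLIVPDNPPYDKGAFRIEINFPAE
YPFKPPKITFKTKIYHPNIDEKGQVCLPVISAENWKPATKTDQVIQSLIALVNDPQPEHP
LRADLAEEYSKDRKKFCKNAEEFTKKYGEKRPVD
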