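{"components":{"sigma2_u":0.3,"sigma2_c":0.1,"sigma2_e":0.6,"h2":0.3,"c2":0.1},"gamma_true":[{"TL1":0.621833333333333,"TL2":0.469788888888889,"TL3":0.453055555555555,"_row":"TL1"},{"TL1":0.469788888888889,"TL2":0.661922222222222,"TL3":0.488744444444444,"_row":"TL2"},{"TL1":0.453055555555555,"TL2":0.488744444444444,"TL3":0.639999999999999,"_row":"TL3"}],"qtl":[{"marker":"snp00020","index":20,"effect":0.262132913139087},{"marker":"snp00040","index":40,"effect":-0.00993995436035548},{"marker":"snp00055","index":55,"effect":0.0109450056127643},{"marker":"snp00059","index":59,"effect":0.0287341279561662},{"marker":"snp00070","index":70,"effect":-0.264915609019383},{"marker":"snp00073","index":73,"effect":0.195694369581006},{"marker":"snp00077","index":77,"effect":-0.0510916539335779},{"marker":"snp00084","index":84,"effect":-0.37291330387617},{"marker":"snp00088","index":88,"effect":-0.13249718321004},{"marker":"snp00094","index":94,"effect":0.0883220703278464},{"marker":"snp00101","index":101,"effect":-0.224587699604718},{"marker":"snp00102","index":102,"effect":-0.124111778368324},{"marker":"snp00106","index":106,"effect":-0.163623043793375},{"marker":"snp00114","index":114,"effect":-0.0289582507973408},{"marker":"snp00125","index":125,"effect":-0.176214905669838},{"marker":"snp00130","index":130,"effect":-0.051823763260389},{"marker":"snp00133","index":133,"effect":0.0453057835297294},{"marker":"snp00138","index":138,"effect":-0.0603218834996383},{"marker":"snp00144","index":144,"effect":-0.0525776504132243},{"marker":"snp00146","index":146,"effect":0.0503401568102783},{"marker":"snp00156","index":156,"effect":-0.0935463425554476},{"marker":"snp00157","index":157,"effect":0.175618332374925},{"marker":"snp00160","index":160,"effect":-0.3490069182047},{"marker":"snp00169","index":169,"effect":-0.0761594852918208},{"marker":"snp00175","index":175,"effect":-0.0360651577243813},{"marker":"snp00180","index":180,"effect":0.0206423512416054},{"marker":"snp00181","index":181,"effect":-0.0228014712270092},{"marker":"snp00185","index":185,"effect":0.225523617160632},{"marker":"snp00186","index":186,"effect":-0.264470396806701},{"marker":"snp00188","index":188,"effect":0.11457106271029}],"seed":424}
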