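(((((((((sp01:3.573240517,sp02:3.573240517):6.370221394,sp03:9.943461911):0.06802010789,(sp04:0.5217964422,sp05:0.5217964422):9.489685577):1.134112159,((sp06:2.114668118,sp07:2.114668118):1.254580342,sp08:3.36924846):7.776345718):9.091747852,((sp09:0.3917140036,sp10:0.3917140036):0.02918591553,sp11:0.4208999192):19.81644211):9.548184879,(sp12:2.944458678,sp13:2.944458678):26.84106823):3.001724109,(sp14:27.89247346,sp15:27.89247346):4.894777559):4.428589243,(((((sp16:8.919301525,sp17:8.919301525):0.9925939444,sp18:9.91189547):0.5793996416,(sp19:0.8445318194,sp20:0.8445318194):9.646763292):10.49177238,(((sp21:6.170145312,sp22:6.170145312):8.489202112,sp23:14.65934742):6.054809393,sp24:20.71415682):0.268910675):13.09246076,sp25:34.07552825):3.140312006):12.78415974,((((sp26:0.9081519863,sp27:0.9081519863):21.20543799,sp28:22.11358998):3.647064262,sp29:25.76065424):17.18993742,sp30:42.95059166):7.049408338);
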