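cdr3b,peptide,label
IRYRHSYHPNWD,RLSTGYRC,0
AVGRQIMMSPKNDFL,YLFHSMGML,0
KQTRTSLWMFDRQREEI,HRCDDKEWT,1
RKQTEIDTSHKCRWLLAE,YFCDDKTM,1
HRDRYNLLALFKQTQK,AYNDDKWC,1
DDDTTQINTTSFIPAM,ENMKVQVQ,0
CLMNFKINMLQCGN,MSADKHYKE,0
TQWTFPIYDLWNQL,THWQQWQEHD,0
SPGMQNHDDCPMRHGK,WEVYTQHRAF,1
YVLACVNPFTYTD,SRVHSDIIL,0
GDDCGVLLWFLE,EWSQVYTQ,1
EEVCQEHIFQDDCAPCLT,VLWYTQLNY,1
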