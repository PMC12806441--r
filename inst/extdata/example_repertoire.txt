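QQPNGPVFTSRKNQQ
NVDQQVQRCGIHE
TVSFNDVHMERQD
CWRAHFGRKISYT
RTIYFNHYMTKLSC
WWIQFKPPQFNNM
ALGPHTWAAGINQYMC
SSVGKKIGNGWFGLL
KMYAFSQKSHTYV
VMKVWERNPWSRN
AECGINWFQNWRD
FNVNFAPQDVDIEH
HIENNCIEDRNDMP
KNQSYYWKAQSWNV
KFLELNEWKKTQR
EKAAELIRSWFEADP
HHKTTMEYFAEQT
DTLGQNHRVDRFTWQS
GYVCISNVINAW
ETMICTEECWMTS
QQINKNCYHKPIARK
YCFPWFLDTMKNNIH
AFIWARICAECCD
NEHNDAVHNCSDVW
TSDCQTGIPVLHY
VNPTDGGIRKCNF
EMHSVRLRFQEHDK
NDQRDEGTLLSDHDGT
EEDRSNGLRPIFDVNR
QYGSNLIHVMIPLPH
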