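>gI_query_01 synthetic prolamin-like
SGVIMNRDSEATYDDDNTQPPQQPFPQQPQKPFPQQPQTPFPQQPQQPFGQQPQQWPQQP
FPEQPPQQPQQPFPQQPQQPLQLQPFPQPQLPYPQPELPYPQPQLPYPQPQPFPQQPQQP
FPQQPQQPFPQQPQQPFYQKPQCPFPQQPQQPFPQQPQQPFPQQPQQPHPQQPQQYFPQQ
PQQPFPQQPQQPFPQQPQQPFPQQPQQPFPQQPQQPFPQRDQSFVKLGGQAGEKALPAID
>gIb_query_01 synthetic Pooideae-like, exact matches ablated
DPGTIQRRNLNIEARQSLFDPQQPFPQQPQQPFPQQPQQPFHQQPQQPFPAQQPDPQQPQ
QPFPQPQQPQQPFPQQPQQPFPQQPQRPFPQQPQQPFPQQPQQPFIQQPQQPFPQQPQQP
FPQQPQQPFPEQDQQPFWQLPQQPFPQQPQQPFPQQPQQIFPQQDQQPFPQQPQQPFPQQ
AQQPFNQQPQQPFPQGPQQPFWQQPQVPFPQQPQQPFPQQPAQQSFPQQPQQPPQQPQQP
FPQQPQQPFPQQNRGKNRAQQPFPEQPKALRK
>gIV_query_01 synthetic unrelated
AALMPLIDRSIKGICRWPEYYVGGVFISGSYHVQIMDRHAIVRIRIDFRVDPYRDPAEGV
RTEVCDITPIRSLQHGERDITMFSAASAITMSVGSANSLGDDKRAVEVDLLTKQSSAASP
DKATPLTLLSINARWANLSKQAGFHLFSSLEPEKASSRLITAEKEPIGPLWTFFMAIMAA
PLIPKIRRSLNPCSAIAPESAGTDGSRLLQTVGHEGRRDHGNLYHN
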