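# Role-recognition rules for gene-cluster detection.
#
# Each rule may give a case-insensitive `product` regex matched against the
# annotated gene product, and/or a `domains` list matched against the gene's
# domain labels (Pfam accession or name). A gene fills a role when either
# evidence matches; domain evidence is listed first because it is the more
# specific signal. Edit or replace this file to adapt the detectors to a
# different annotation vocabulary.
roles:
  wza:
    product: '\bwza\b|polysaccharide export protein wza'
    domains: [pfam02563, Poly_export]
  wzc:
    product: '\bwzc\b|tyrosine-protein kinase wzc'
  wzx:
    product: '\bwzx\b|flippase'
  wzy:
    product: '\bwzy\b|o-antigen polymerase'
  kpsD:
    product: '\bkpsd\b'
  kpsE:
    product: '\bkpse\b'
  kpsM:
    product: '\bkpsm\b'
  kpsT:
    product: '\bkpst\b'
  wspA:
    product: '\bwspa\b|methyl-accepting chemotaxis protein wsp'
    domains: [pfam00015, MCPsignal]
  wspB:
    product: '\bwspb\b'
  wspC:
    product: '\bwspc\b'
  wspD:
    product: '\bwspd\b'
  wspE:
    product: '\bwspe\b'
  wspF:
    product: '\bwspf\b'
ggdef:
  domains: [pfam00990, GGDEF]
pilz:
  domains: [pfam07238, PilZ]
hlyd:
  domains: [pfam13437, HlyD_3, pfam13533, Biotin_lipoyl_2, pfam16576, HlyD_D23]
abc_transporter:
  product: 'abc[- ]transporter'
  domains: [pfam00005, ABC_tran]
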