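# Cold-shock gene-family census rules: one entry per family, matched against
# annotated gene products (case-insensitive regex) and/or domain labels.
# The family set follows the standard bacterial cold-shock complement
# (pyruvate dehydrogenase, DNA gyrase, chaperones, desaturases, cold-shock
# proteins, translation/transcription factors, trehalose synthesis, RNA
# decay, ribosome maturation and hibernation).
aceE:
  product: 'pyruvate dehydrogenase (e1|subunit e1)|\bacee\b'
aceF:
  product: 'dihydrolipo\w* acetyltransferase|pyruvate dehydrogenase .*e2|\bacef\b'
csp-family:
  product: 'cold[- ]shock( dna[- ]binding)? protein|\bcsp[a-z]?\b'
deaD:
  product: 'atp-dependent rna helicase (dead|csda)|dead[- /]box rna helicase|\bdead\b'
desAB:
  product: 'fatty acid desaturase|\bdes[ab]\b'
dnaA:
  product: 'chromosomal replication initiat\w+ protein|\bdnaa\b'
gyrA:
  product: 'dna gyrase,? subunit a|\bgyra\b'
dnaK:
  product: 'chaperone protein dnak|molecular chaperone dnak|\bdnak\b|hsp70'
dnaJ:
  product: 'chaperone protein dnaj|molecular chaperone dnaj|\bdnaj\b|hsp40'
hupB:
  product: 'dna-binding protein hu|\bhupb\b'
infA/IF-1:
  product: 'translation initiation factor (if-?1\b|1\b)|\binfa\b'
infB/IF-2:
  product: 'translation initiation factor (if-?2\b|2\b)|\binfb\b'
infC/IF-3:
  product: 'translation initiation factor (if-?3\b|3\b)|\binfc\b'
nusA:
  product: 'transcription (termination|elongation|termination/antitermination) (factor|protein) nusa|\bnusa\b'
otsA:
  product: 'trehalose-6-phosphate synthase|\botsa\b'
pnp:
  product: 'polyribonucleotide nucleotidyltransferase|polynucleotide phosphorylase|\bpnp\b'
rnr:
  product: 'ribonuclease r\b|exoribonuclease r|\brnr\b'
rbfA:
  product: 'ribosome-binding factor a|\brbfa\b'
recA:
  product: 'protein reca|recombinase (a\b|reca)|\breca\b'
tig:
  product: 'trigger factor|\btig\b'
yfiA:
  product: 'ribosome[- ]associated (inhibitor|protein)|ribosome hibernation|\byfia\b'
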