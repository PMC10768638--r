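Drop the published supplementary graph files here to enable the two
worked-example acceptance tests (they fail cleanly while these are absent;
none of the package's other functionality needs them):

  parp_cq_big.txt          binding interaction graph, PARP1 catalytic domain
                           + 8-chloroquinazolinone inhibitor
  tace_ts_big.txt          binding interaction graph, TACE catalytic domain
                           + thiomorpholine sulfonamide hydroxamate inhibitor
  ah003339_wfsg.txt        weighted full stem graph, tRNA fragment AH003339
  ah003339_stems.txt       stem legend: one "i j length" row per vertex
  ah003339_reference.txt   reference fold as an "i j" pair list
  ab041850_wfsg.txt        weighted full stem graph, tRNA fragment AB041850
  ab041850_stems.txt
  ab041850_reference.txt

Adjacency files use the package dialect read by read_adjacency(): a square
whitespace- or comma-delimited 0/1 matrix with vertex weights on the
diagonal (contact potentials for the BIGs, stem lengths for the WFSGs).
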