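# ten-row table with a hand-enumerated expected selection:
#   g01 expressed + FC gate on 0-3 h            -> selected
#   g02 fails the RPKM gate                     -> rejected
#   g03 expressed at 3 h + FC gate on 3-12 h    -> selected
#   g04 sustained up-regulation, both FDR < .05 -> selected
#   g05 sustained FCs but second FDR fails      -> rejected
#   g06 FC > 1 but its FDR fails                -> rejected
#   g07 RPKM exactly 1 (gate is strict)         -> rejected
#   g08 down then strongly up on 3-12 h         -> selected
#   g09 Ca-sensitive, sub-threshold FC          -> selected only when relaxed
#   g10 Ca-sensitive but down-regulated         -> rejected in both modes
deg_fixture <- function() {
  data.frame(
    gene_id = sprintf("g%02d", 1:10),
    rpkm_3h    = c(5,   0.5, 2,   3,   3,   3,   1,   2,   2,   2),
    rpkm_12h   = c(5,   0.5, 0.1, 4,   4,   4,   1,   2,   2,   2),
    log2fc_0_3 = c(1.5, 3,   0,   0.5, 0.5, 1.5, 2,  -2,   0.5, -0.5),
    log2fc_3_12= c(0,   3,   1.2, 0.6, 0.6, 0,   2,   3,   0.2, -0.2),
    fdr_0_3    = c(0.01, 0.001, 0.5, 0.01, 0.01, 0.2, 0.01, 0.01, 0.01, 0.01),
    fdr_3_12   = c(0.9, 0.001, 0.01, 0.02, 0.2, 0.9, 0.01, 0.04, 0.2, 0.01),
    ca_sensitive = c(rep(FALSE, 8), TRUE, TRUE),
    stringsAsFactors = FALSE)
}

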