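# independent recursive reference: u computed from the full node
# distance matrix rather than postorder accumulation
red_reference <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  dn <- ape::dist.nodes(tree)
  red <- rep(NA_real_, nn)
  recurse_children <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    for (ch in kids) {
      if (ch <= nt) {
        red[ch] <<- 1
      } else {
        leaves <- phangorn::Descendants(tree, ch, "tips")[[1]]
        u <- mean(dn[node, leaves])
        red[ch] <<- red[node] + (1 - red[node]) * dn[node, ch] / u
        recurse_children(ch)
      }
    }
  }
  red[nt + 1] <- 0
  recurse_children(nt + 1)
  red
}
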