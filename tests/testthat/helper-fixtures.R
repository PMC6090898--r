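# Shared synthetic layout fixtures.

# annotation helper: equally spaced genes on one contig
grid_ann <- function(n, strand = "+", len = 100L, gap = 20L,
                     contig = "c1", offset = 50L) {
  starts <- offset + (seq_len(n) - 1L) * (len + gap)
  genome_annotation(sprintf("g%02d", seq_len(n)), contig,
                    starts, starts + len, rep_len(strand, n))
}

# plateau coverage over gene spans (+ optional intergenic fill)
plateau_track <- function(ann, levels, L = NULL, fill_gaps = TRUE) {
  if (is.null(L)) L <- max(ann$end) + 50L
  trk <- coverage_track(setNames(L, ann$contig[1]))
  for (i in seq_len(nrow(ann))) {
    st <- if (ann$strand[i] == "+") "plus" else "minus"
    trk[[1]][[st]][(ann$start[i] + 1):ann$end[i]] <- levels[i]
  }
  if (fill_gaps) {
    for (i in seq_len(nrow(ann) - 1)) {
      if (ann$strand[i] != ann$strand[i + 1]) next
      st <- if (ann$strand[i] == "+") "plus" else "minus"
      span <- (ann$end[i] + 1):ann$start[i + 1]
      trk[[1]][[st]][span] <- min(levels[i], levels[i + 1])
    }
  }
  trk
}
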