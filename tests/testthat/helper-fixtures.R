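# Small in-code fixtures for the genotyping tests.

# quick amplicon: a read vector with sample/replicate metadata
amp <- function(sample_id, replicate, reads) {
  list(sample_id = sample_id, replicate = replicate, reads = reads)
}

# build a cluster data.frame directly (already step-1-labelled states)
clusters_df <- function(sequence, count, label, state,
                        n_assigned = sum(count)) {
  data.frame(sequence = sequence, count = count,
             frequency = count / n_assigned, label = label, state = state,
             stringsAsFactors = FALSE)
}

# compare a genotype_calls object against simulator truth; returns the
# fraction of samples whose called allele set equals the true allele set
recovery_fraction <- function(res, study) {
  seq2pool <- setNames(names(study$pool$alleles),
                       unname(study$pool$alleles))
  truth <- lapply(study$population, function(g) sort(g$alleles))
  names(truth) <- vapply(study$population, `[[`, character(1), "sample_id")
  ok <- vapply(names(truth), function(sid) {
    cc <- res$calls[[sid]]
    if (is.null(cc)) return(FALSE)
    seqs <- res$catalog$sequence[match(cc$alleles, res$catalog$allele)]
    identical(sort(unname(seq2pool[seqs])), truth[[sid]])
  }, logical(1))
  mean(ok)
}
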