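# Shared fixture builders: all inputs are generated in code at test time.

tmp_lines <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

tmp_tsv <- function(df) {
  f <- tempfile(fileext = ".tsv")
  adrepo::write_tsv(df, f)
  f
}

gwas_lines <- function(rows, sep = "\t") {
  header <- paste(c("gene_symbol", "snp_id", "odds_ratio", "p_value",
                    "initial_n", "replication_n", "pubmed_id"),
                  collapse = sep)
  c(header, vapply(rows, paste, character(1), collapse = sep))
}

# Independent brute-force oracle for the metabolite-protein filter: a
# plain double loop over link rows, no set machinery shared with the
# implementation.
brute_collect <- function(links, changed, min_links) {
  proteins <- unique(links$uniprot_id)
  out <- list()
  for (p in proteins) {
    linked <- character(0)
    linked_changed <- character(0)
    for (i in seq_len(nrow(links))) {
      if (links$uniprot_id[i] == p) {
        m <- links$metabolite_id[i]
        if (!m %in% linked) linked <- c(linked, m)
        if (m %in% changed && !m %in% linked_changed) {
          linked_changed <- c(linked_changed, m)
        }
      }
    }
    if (length(linked_changed) >= min_links) {
      out[[p]] <- c(n = length(linked_changed), N = length(linked))
    }
  }
  out
}

# A random link table with ids drawn from fixed pools.
random_links <- function(n_met, n_prot, n_rows) {
  data.frame(
    metabolite_id = sprintf("M%02d", sample.int(n_met, n_rows,
                                                replace = TRUE)),
    uniprot_id = sprintf("P%02d", sample.int(n_prot, n_rows,
                                             replace = TRUE)),
    stringsAsFactors = FALSE)
}
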