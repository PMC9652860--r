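# Shared fixture builders. Everything is generated in code; no data files.

# small random two-layer cohort with a matching relation catalogue
random_cohort <- function(n = 20, n_kin = 5, n_sub = 8, n_rel = 10,
                          seed = 1, two_states = TRUE) {
  set.seed(seed)
  states <- if (two_states) rep(c(1L, 2L), length.out = n) else rep(1L, n)
  ids <- sprintf("S%02d", seq_len(n))
  kin <- sprintf("K%02d", seq_len(n_kin))
  subg <- sprintf("G%02d", seq_len(n_sub))
  site <- paste0(sample(c("S", "T", "Y"), n_sub, replace = TRUE),
                 sample(1:500, n_sub))
  prot <- matrix(rnorm(n * n_kin), n, n_kin, dimnames = list(ids, kin))
  phos <- matrix(rnorm(n * n_sub), n, n_sub,
                 dimnames = list(ids, paste0(subg, "_", site)))
  rel_idx <- sample(n_sub, n_rel, replace = TRUE)
  relations <- data.frame(kinase = sample(kin, n_rel, replace = TRUE),
                          substrate_gene = subg[rel_idx],
                          substrate_site = site[rel_idx],
                          source = "test", stringsAsFactors = FALSE)
  relations <- relations[!duplicated(relations[1:3]), ]
  list(protein = cohort_matrix(prot, states, "protein"),
       phosphosite = cohort_matrix(phos, states, "phosphosite"),
       relations = relations, states = states)
}

write_tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# tiny 3-sample cohort fixture tree on disk for manifest-reader tests
write_mini_cohort <- function(dir, states = c(1, 1, 2), extra_gene_sample = NULL,
                              drugs = list(drugA = c(10, 20, 30))) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- paste0("P", seq_along(states))
  for (i in seq_along(ids)) {
    genes <- c("A,1.0", "B,2.0")
    if (!is.null(extra_gene_sample) && i == extra_gene_sample) {
      genes <- c(genes, "C,3.0")
    }
    writeLines(genes, file.path(dir, paste0(ids[i], "_prot.csv")))
    writeLines(c("A_S1,0.5", "B_T2,1.5"), file.path(dir, paste0(ids[i], "_phos.csv")))
  }
  man <- data.frame(sample_id = ids, state = states,
                    protein_file = paste0(ids, "_prot.csv"),
                    phospho_file = paste0(ids, "_phos.csv"))
  for (d in names(drugs)) man[[d]] <- drugs[[d]]
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE, quote = FALSE)
  path
}
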