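# Shared fixtures, built in code.

# A dataset whose rows come in well-separated groups: group i's genes sit
# around offset 10 * i with small deterministic jitter.
make_grouped_dataset <- function(group_sizes, d = 4, id = "toy",
                                 role = "unspecified", jitter = 0.1) {
  g <- sum(group_sizes)
  values <- matrix(0, g, d)
  row <- 1
  for (i in seq_along(group_sizes)) {
    base <- 10 * i + seq_len(d)
    for (j in seq_len(group_sizes[i])) {
      values[row, ] <- base + jitter * sin(seq_len(d) + row)
      row <- row + 1
    }
  }
  expression_dataset(values, dataset_id = id,
                     gene_ids = paste0("g", seq_len(g)), role = role)
}

# A tiny deterministic dataset with arbitrary values.
make_plain_dataset <- function(values, id = "toy", role = "unspecified",
                               channel = "unknown") {
  expression_dataset(as.matrix(values), dataset_id = id,
                     gene_ids = paste0("g", seq_len(nrow(as.matrix(values)))),
                     role = role, channel = channel)
}

# Hard partition matrix from a label vector, bypassing any clustering.
make_partition <- function(labels, k, method = "manual", id = "toy") {
  uncles:::partition_matrix(as.integer(labels), k, method, id)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Write a small TSV expression file and return its path.
write_tsv_fixture <- function(lines, name = "expr.tsv") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
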