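# Shared fixture builders. Everything is generated in code at test time;
# the only file fixture is the toy anatomical schema shipped in extdata.

toy_schema_path <- function() {
  system.file("extdata", "toy_schema.tsv", package = "adrhier")
}

# minimal 4-term schema: two organs under two systems plus a MISC term
tiny_schema <- function() {
  anatomical_schema(data.frame(
    side_effect = c("nausea", "vomiting", "rash", "pain"),
    organ = c("stomach", "stomach", "skin", "MISC"),
    sub_system = c("GI", "GI", "integument", "MISC"),
    system = c("digestive", "digestive", "integumentary", "MISC"),
    stringsAsFactors = FALSE
  ))
}

# random binary drug x label matrix with named dims
random_assoc <- function(n_drugs, n_labels, density = 0.2,
                         level = "side_effect",
                         labels = sprintf("se%02d", seq_len(n_labels))) {
  m <- matrix(rbinom(n_drugs * n_labels, 1L, density), n_drugs, n_labels,
              dimnames = list(sprintf("d%03d", seq_len(n_drugs)), labels))
  association_matrix(m, level = level)
}

# random schema mapping n_se side effects into n_organs organs (each
# organ non-empty), organs nested into ceiling(n_organs/2) sub-systems
# and 2 systems
random_schema <- function(n_se, n_organs) {
  stopifnot(n_se >= n_organs)
  organs <- sprintf("org%02d", seq_len(n_organs))
  assign_org <- c(organs, sample(organs, n_se - n_organs, replace = TRUE))
  assign_org <- sample(assign_org)
  n_sub <- max(1L, ceiling(n_organs / 2))
  org_sub <- setNames(sprintf("sub%02d", rep(seq_len(n_sub),
                                             length.out = n_organs)), organs)
  sub_sys <- setNames(sprintf("sys%d", rep(1:2, length.out = n_sub)),
                      sprintf("sub%02d", seq_len(n_sub)))
  anatomical_schema(data.frame(
    side_effect = sprintf("se%02d", seq_len(n_se)),
    organ = assign_org,
    sub_system = unname(org_sub[assign_org]),
    system = unname(sub_sys[org_sub[assign_org]]),
    stringsAsFactors = FALSE
  ))
}

# write a SIDER-dialect meddra_all_se fixture; rows is a data.frame with
# columns drug, type, se (other ids synthesized)
write_sider_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  lines <- sprintf("CID1%07d\tCID0%07d\tC%07d\t%s\tC%07d\t%s",
                   as.integer(factor(rows$drug)),
                   as.integer(factor(rows$drug)),
                   seq_len(nrow(rows)), rows$type, seq_len(nrow(rows)),
                   rows$se)
  writeLines(lines, path)
  path
}

# small separable 1-label classification bundle: two Gaussian clusters
separable_bundle <- function(n_per_class = 20, d = 5, shift = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
             matrix(rnorm(n_per_class * d, mean = shift), ncol = d))
  ids <- sprintf("d%03d", seq_len(2 * n_per_class))
  dimnames(x) <- list(ids, paste0("f", seq_len(d)))
  y <- matrix(rep(0:1, each = n_per_class), ncol = 1,
              dimnames = list(ids, "lab"))
  list(x = x, y = y, drug_ids = ids)
}
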