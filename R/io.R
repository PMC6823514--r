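## Configuration, TSV plumbing and the end-to-end pipeline drivers. The
## package's analyses are driven from R (or Rscript) through these functions;
## every output table carries a header block with the package version, a
## configuration hash and the master seed, so results are traceable.

#' Write a TSV report with a traceability header
#'
#' Tab-separated, UTF-8, '.' decimal. The header block (lines starting with
#' `#`) records the package version, a hash of the configuration used, and
#' the master seed.
#'
#' @param tab data.frame.
#' @param file output path.
#' @param seed master seed to record (optional).
#' @param config object whose serialized md5 is recorded (optional).
#' @param extra_header extra comment lines (without the `#`).
#' @export
write_tsv_report <- function(tab, file, seed = NULL, config = NULL,
                             extra_header = character()) {
  con <- base::file(file, "w", encoding = "UTF-8")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("mmbscan"))
  writeLines(paste0("# mmbscan ", ver), con)
  if (!is.null(config)) {
    tf <- tempfile(); on.exit(unlink(tf), add = TRUE)
    saveRDS(config, tf)
    writeLines(paste0("# config_hash: ", unname(tools::md5sum(tf))), con)
  }
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  for (h in extra_header) writeLines(paste0("# ", h), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a plain-text key-value run configuration
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored.
#' Values that parse as numbers become numeric; comma-separated values become
#' vectors. Keys with a `path` suffix are checked for existence.
#'
#' @param file configuration path.
#' @return named list of class `run_config`.
#' @export
read_run_config <- function(file) {
  lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[2]); val <- trimws(kv[3])
    parts <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  for (key in grep("_path$", names(out), value = TRUE)) {
    if (!file.exists(out[[key]]))
      stop("config path does not exist: ", key, " = ", out[[key]])
  }
  structure(out, class = "run_config")
}

#' Run the alpha-estimation pipeline on a directory of intron FASTAs
#'
#' Reads per-intron pairwise FASTA alignments listed in a manifest TSV
#' (columns `gene`, `class`, `file`, ordered by intron position within each
#' gene), filters them, estimates alpha, and writes the report tables.
#'
#' @param manifest manifest TSV path (`gene`, `class`, `file`; paths relative
#'   to the manifest's directory).
#' @param out_dir output directory.
#' @param n_boot double-bootstrap replicates.
#' @param seed master seed.
#' @param min_total gene-level column floor.
#' @return the `alpha_fit`, invisibly.
#' @export
run_alpha_pipeline <- function(manifest, out_dir, n_boot = 1000, seed = 1,
                               min_total = 1000) {
  man <- utils::read.delim(manifest, comment.char = "#")
  stopifnot(all(c("gene", "class", "file") %in% names(man)))
  base <- dirname(manifest)
  genes <- lapply(split(man, man$gene), function(rows) {
    intron_gene(rows$gene[1], rows$class[1],
                lapply(file.path(base, rows$file), read_alignment_fasta))
  })
  iset <- intron_set(unname(genes))
  fit <- estimate_alpha(iset, n_boot = n_boot, seed = seed,
                        min_total = min_total)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_alpha_tsv(fit, file.path(out_dir, "alpha_estimates.tsv"), seed = seed)
  if (!is.null(fit$audit))
    write_tsv_report(fit$audit, file.path(out_dir, "filter_ledger.tsv"),
                     seed = seed)
  for (cl in c("X", "Y", "A"))
    write_bootstrap_tsv(fit$rates[[cl]],
                        file.path(out_dir, paste0("rate_", cl, "_bootstrap.tsv")),
                        seed = seed)
  invisible(fit)
}

#' Run the turnover-dating pipeline on synthetic or prepared data
#'
#' The simulation-backed end of the package: generates (or accepts) a codon
#' gene set, runs [turnover_scan()], and writes the scan table and interval
#' summary.
#'
#' @param genes list of codon alignments (see [turnover_scan()]).
#' @param tree a `species_tree` in Myr units with lineage tags.
#' @param grid scenario grid.
#' @param groups named character vector (measured tips -> groups).
#' @param focal,reference group tags.
#' @param out_dir output directory.
#' @param ... passed to [turnover_scan()].
#' @param seed master seed.
#' @return the `turnover_scan`, invisibly.
#' @export
run_turnover_pipeline <- function(genes, tree, grid, groups, focal, reference,
                                  out_dir, seed = 1, ...) {
  scan <- turnover_scan(genes, tree, grid, groups, focal = focal,
                        reference = reference, seed = seed, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_scan_tsv(scan, file.path(out_dir, "turnover_scan.tsv"), seed = seed)
  write_tsv_report(scan$intervals, file.path(out_dir, "intervals.tsv"),
                   seed = seed)
  invisible(scan)
}

#' Demo: a complete desk-scale turnover analysis with known truth
#'
#' Builds a small squamate-like tree, generates a codon gene set in which the
#' focal lineage retained the ancestral XY system for a known time, scans it,
#' and returns the `turnover_scan` together with the truth. Runs in about a
#' minute at the default sizes.
#'
#' @param true_T true retention time (Myr).
#' @param true_alpha true male mutation bias in the focal lineage.
#' @param n_genes genes in the observed set.
#' @param n_boot observed codon-bootstrap replicates.
#' @param n_sim simulation replicates per scenario.
#' @param seed master seed.
#' @param out_dir optional output directory for the TSV reports.
#' @return list: `scan` (a `turnover_scan`), `truth` (data.frame).
#' @export
run_demo <- function(true_T = 80, true_alpha = 4, n_genes = 50, n_boot = 50,
                     n_sim = 20, seed = 1, out_dir = NULL) {
  setup <- demo_setup()
  truth <- lineage_scenario(
    rbind(data.frame(lineage = "agamid", alpha = true_alpha,
                     retention_T = true_T),
          data.frame(lineage = "pleurodont", alpha = 6, retention_T = 170)),
    system_age = 170)
  spec <- codon_synth_spec(setup$tree, truth, n_genes = n_genes,
                           gene_codons = 333, seed = derive_seed(seed, 11))
  ds <- gen_codon_dataset(spec)
  grid <- scenario_grid("agamid", true_alpha, system_age = 170, step = 10,
                        t_max = 150,
                        fixed = data.frame(lineage = "pleurodont", alpha = 6,
                                           retention_T = 170))
  scan <- turnover_scan(ds$genes, setup$tree, grid, setup$groups,
                        focal = "agamid", reference = "snake",
                        n_boot = n_boot, n_sim = n_sim, sim_length = 1000,
                        seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_scan_tsv(scan, file.path(out_dir, "turnover_scan.tsv"), seed = seed)
    truth_report(ds, file.path(out_dir, "truth.tsv"))
  }
  list(scan = scan, truth = truth_report(ds))
}

## Internal: the 10-taxon squamate-like demo tree (Myr, ultrametric) with
## lineage tags. Split times follow the study system's coarse timescale:
## amniote root 312 Ma, snake/iguanian split 190 Ma, agamid/pleurodont split
## 165 Ma, sex chromosome system age 170 Ma.
demo_setup <- function() {
  nwk <- paste0(
    "((outg1:280,outg2:280):32,((snake1:60,(snake2:40,snake3:40):20):130,",
    "((agamid1:50,(agamid2:30,agamid3:30):20):115,",
    "(pleuro1:70,pleuro2:70):95):25):122);")
  phy <- ape::read.tree(text = nwk)
  lineages <- c(outg1 = "outgroup", outg2 = "outgroup",
                snake1 = "snake", snake2 = "snake", snake3 = "snake",
                agamid1 = "agamid", agamid2 = "agamid", agamid3 = "agamid",
                pleuro1 = "pleurodont", pleuro2 = "pleurodont")
  tree <- species_tree(phy, units = "myr", lineages = lineages)
  groups <- lineages[c("snake1", "snake2", "snake3", "agamid1", "agamid2",
                       "agamid3", "pleuro1", "pleuro2")]
  list(tree = tree, groups = groups)
}
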