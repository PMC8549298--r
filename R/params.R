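#' Assembly parameters
#'
#' Builds the parameter set controlling the whole pipeline. The sequencing
#' platform sets the defaults the read error profile calls for: the minimum
#' overlap identity is 0.95 for PacBio HiFi reads and 0.75 for PacBio CLR and
#' ONT reads, and raw-read error correction defaults to on for the noisy
#' platforms (CLR/ONT) and off for HiFi.
#'
#' @param platform Sequencing platform, one of `"hifi"`, `"clr"`, `"ont"`.
#' @param min_ovlp_len Minimum overlap length in bases for retained read
#'   overlaps (default 1000).
#' @param min_identity Minimum overlap identity in `(0, 1]`. `NULL` picks the
#'   platform default (0.95 hifi, 0.75 clr/ont).
#' @param snp_filter_k Heterozygous-SNP tolerance of the optional overlap
#'   filter on the super-read graph: an edge is removed when its overlap
#'   region contains more than `snp_filter_k` heterozygous sites (default 0,
#'   i.e. any heterozygous site removes the edge).
#' @param max_phasing_coverage Per-column read coverage cap of the wMEC
#'   dynamic program (default 20); columns above the cap are downsampled,
#'   keeping the longest-spanning reads.
#' @param tip_max_nodes Maximum number of nodes in a dead-end branch removed
#'   as a tip from the super-read graph (default 2).
#' @param min_contig_len Minimum final contig length in bases (default 1000).
#' @param correct_raw_reads Correct reads within each phase group before super
#'   read construction. `NULL` picks the platform default (on for clr/ont,
#'   off for hifi).
#' @param snp_edge_filter Enable SNP-based spurious edge removal on the
#'   super-read graph (default off; recommended for small genomes or highly
#'   polymorphic regions such as MHC).
#' @param polish_final Polish final contigs with the groups' reads (default
#'   on). Super-read end regions, which carry elevated error, sit in the
#'   contig interior after merging and only full-coverage polishing repairs
#'   them; the step matters most below about 20x per haplotype but is cheap
#'   enough to keep on. Set `FALSE` to skip.
#' @param polish_rounds Pileup polishing rounds for the ad hoc reference and
#'   super reads (default 2).
#' @param sr_min_ovlp_len,sr_min_identity Stricter thresholds of the
#'   super-read overlap graph (defaults 3000 bp, and identity 0.98 for HiFi /
#'   0.95 for CLR and ONT): super reads are long and near error-free, so
#'   near-perfect identity is required of their overlaps; the noisy-platform
#'   default allows for the elevated residual error near super-read ends.
#' @param sr_contain_identity Minimum identity for a super read to be
#'   absorbed as contained in another (default 0.998). Must be stricter than
#'   `sr_min_identity`: at typical heterozygosity a super read's
#'   cross-haplotype counterpart is about 99\% identical, and absorbing into
#'   it would delete a haplotype block.
#' @param max_hang,int_frac Overlap classification constants: an overlap is an
#'   internal match when its total overhang exceeds
#'   `min(max_hang, int_frac * block_len)` (defaults 1000 and 0.8).
#' @param rng_seed Seed for every stochastic step (phasing downsampling
#'   tie-breaks); per-cluster seeds are derived from it.
#' @param threads Number of worker processes for per-cluster work. Results are
#'   byte-identical for any thread count.
#'
#' @return A list of class `haplobook_params`.
#' @export
#' @examples
#' assembly_params("hifi")$min_identity   # 0.95
#' assembly_params("ont")$min_identity    # 0.75
assembly_params <- function(platform = c("hifi", "clr", "ont"),
                            min_ovlp_len = 1000L,
                            min_identity = NULL,
                            snp_filter_k = 0L,
                            max_phasing_coverage = 20L,
                            tip_max_nodes = 2L,
                            min_contig_len = 1000L,
                            correct_raw_reads = NULL,
                            snp_edge_filter = FALSE,
                            polish_final = NULL,
                            polish_rounds = 2L,
                            sr_min_ovlp_len = 3000L,
                            sr_min_identity = NULL,
                            sr_contain_identity = 0.998,
                            max_hang = 1000L,
                            int_frac = 0.8,
                            rng_seed = 1L,
                            threads = 1L) {
  platform <- match.arg(platform)
  if (is.null(min_identity)) {
    min_identity <- if (platform == "hifi") 0.95 else 0.75
  }
  if (is.null(correct_raw_reads)) {
    correct_raw_reads <- platform != "hifi"
  }
  if (is.null(sr_min_identity)) {
    # super reads from noisy platforms keep elevated error near their ends,
    # where the inter-cluster overlaps live
    sr_min_identity <- if (platform == "hifi") 0.98 else 0.95
  }
  p <- list(
    platform = platform,
    min_ovlp_len = as.integer(min_ovlp_len),
    min_identity = as.numeric(min_identity),
    snp_filter_k = as.integer(snp_filter_k),
    max_phasing_coverage = as.integer(max_phasing_coverage),
    tip_max_nodes = as.integer(tip_max_nodes),
    min_contig_len = as.integer(min_contig_len),
    correct_raw_reads = isTRUE(correct_raw_reads),
    snp_edge_filter = isTRUE(snp_edge_filter),
    polish_final = if (is.null(polish_final)) NULL else isTRUE(polish_final),
    polish_rounds = as.integer(polish_rounds),
    sr_min_ovlp_len = as.integer(sr_min_ovlp_len),
    sr_min_identity = as.numeric(sr_min_identity),
    sr_contain_identity = as.numeric(sr_contain_identity),
    max_hang = as.integer(max_hang),
    int_frac = as.numeric(int_frac),
    rng_seed = as.integer(rng_seed),
    threads = as.integer(threads),
    # minimizer sketch / alignment band settings derived from the platform
    k = 15L,
    w = if (platform == "hifi") 10L else 5L,
    band_frac = if (platform == "hifi") 0.05 else 0.15
  )
  validate_params(p)
  structure(p, class = "haplobook_params")
}

validate_params <- function(p) {
  if (!(p$min_identity > 0 && p$min_identity <= 1)) {
    abort(sprintf("min_identity must be in (0, 1], got %s", p$min_identity))
  }
  if (p$min_ovlp_len < 1L) abort("min_ovlp_len must be >= 1")
  if (p$snp_filter_k < 0L) abort("snp_filter_k must be >= 0")
  if (p$max_phasing_coverage < 2L || p$max_phasing_coverage > 25L) {
    abort("max_phasing_coverage must be in [2, 25]")
  }
  if (p$polish_rounds < 0L) abort("polish_rounds must be >= 0")
  if (p$tip_max_nodes < 0L) abort("tip_max_nodes must be >= 0")
  if (!(p$sr_min_identity > 0 && p$sr_min_identity <= 1)) {
    abort("sr_min_identity must be in (0, 1]")
  }
  if (p$threads < 1L) abort("threads must be >= 1")
  invisible(p)
}

#' Load parameters from a config file and/or overrides
#'
#' The configuration file is flat `key = value` text (one pair per line,
#' `#` comments allowed). Values given as `...` override file values, which
#' override the platform defaults. Unknown keys are rejected.
#'
#' @param path Path to a config file, or `NULL` for none.
#' @param ... Named overrides, as accepted by [assembly_params()].
#' @return A `haplobook_params` object.
#' @export
load_params <- function(path = NULL, ...) {
  file_args <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) abort(sprintf("malformed config line: '%s'", ln))
      file_args[[trimws(kv[1])]] <- parse_config_value(trimws(kv[2]))
    }
  }
  overrides <- list(...)
  args <- utils::modifyList(file_args, overrides)
  known <- setdiff(names(formals(assembly_params)), "...")
  bad <- setdiff(names(args), known)
  if (length(bad) > 0) {
    abort(sprintf("unknown parameter key(s): %s", paste(bad, collapse = ", ")))
  }
  do.call(assembly_params, args)
}

parse_config_value <- function(x) {
  if (tolower(x) %in% c("true", "on", "yes")) return(TRUE)
  if (tolower(x) %in% c("false", "off", "no")) return(FALSE)
  n <- suppressWarnings(as.numeric(x))
  if (!is.na(n)) return(n)
  x
}

#' @export
print.haplobook_params <- function(x, ...) {
  cat("<haplobook_params>\n")
  cat(sprintf("  platform: %s (k=%d, w=%d)\n", x$platform, x$k, x$w))
  cat(sprintf("  overlaps: min length %d bp, min identity %.2f\n",
              x$min_ovlp_len, x$min_identity))
  cat(sprintf("  super-read graph: min length %d bp, min identity %.2f\n",
              x$sr_min_ovlp_len, x$sr_min_identity))
  cat(sprintf("  phasing: coverage cap %d; correction %s; SNP edge filter %s\n",
              x$max_phasing_coverage,
              if (x$correct_raw_reads) "on" else "off",
              if (x$snp_edge_filter) "on" else "off"))
  cat(sprintf("  contigs: min length %d bp; final polish %s\n",
              x$min_contig_len,
              if (isFALSE(x$polish_final)) "off" else "on"))
  invisible(x)
}
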