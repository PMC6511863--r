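#' @title File dialects
#' @description
#' All on-disk dialects in one place.  Coordinates are always Angstrom and
#' energies kBT at 310 K in outputs; force constants are kJ mol^-1 nm^-2 on
#' input (the restraint-metadata convention).
#' \itemize{
#'   \item window metadata: whitespace-delimited text, one line per window:
#'     `series_path  center_A  k_kJ_mol_nm2`;
#'   \item window series: two-column whitespace text
#'     `frame_index  delta_rmsd_A` (COLVAR-like);
#'   \item alchemical samples: tab-separated
#'     `lambda_from  lambda_to  direction  dU_kBT` with direction
#'     `forward`/`backward`;
#'   \item fixtures: key-value text, `[section]` headers and `key: value`
#'     lines, `#` comments.
#' }
#' @name polfid-io
NULL

# parse a [section] / key: value config file into a named list of named lists
read_kv_config <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      out[[section]] <- list()
    } else if (grepl(":", ln, fixed = TRUE)) {
      if (is.null(section)) stop("key outside any [section] in ", file)
      key <- trimws(sub(":.*$", "", ln))
      val <- trimws(sub("^[^:]*:", "", ln))
      if (key %in% names(out[[section]]))
        out[[section]][[key]] <- c(out[[section]][[key]], val)
      else out[[section]][[key]] <- val
    } else {
      stop("unparseable line in ", file, ": ", ln)
    }
  }
  out
}

# parse a profile fixture file into named ref_profile objects
read_profile_config <- function(file) {
  cfg <- read_kv_config(file)
  lapply_names <- names(cfg)
  profs <- lapply(lapply_names, function(key) {
    sect <- cfg[[key]]
    domain <- as.numeric(strsplit(trimws(sect$domain), "\\s+")[[1]])
    anch <- do.call(rbind, lapply(sect$anchor, function(a)
      as.numeric(strsplit(trimws(a), "\\s+")[[1]])))
    parts <- strsplit(key, "/", fixed = TRUE)[[1]]
    build_reference_profile(anch, domain = domain,
                            species = parts[1], path = parts[2])
  })
  names(profs) <- lapply_names
  profs
}

#' Write umbrella-window series and metadata files
#'
#' Writes one two-column series file per window (all samples, including the
#' burn-in segment) and a metadata file listing
#' `series_path  center_A  k_kJ_mol_nm2`.
#'
#' @param windows list of [`window_series`][sample_window]
#' @param dir output directory (created if missing)
#' @param prefix series file-name prefix
#' @return path of the metadata file, invisibly
#' @export
write_windows <- function(windows, dir, prefix = "window") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- file.path(dir, paste0(prefix, "_metadata.txt"))
  lines <- character(length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    path <- file.path(dir, sprintf("%s_%03d.dat", prefix, i))
    utils::write.table(data.frame(frame = seq_along(w$samples) - 1L,
                                  delta_rmsd = w$samples),
                       path, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    lines[i] <- sprintf("%s %.6f %.6g", path, w$spec$center, w$spec$k)
  }
  writeLines(lines, meta)
  invisible(meta)
}

#' Read umbrella windows from metadata + series files
#'
#' @param metadata_file whitespace-delimited metadata file
#'   (`series_path center_A k_kJ_mol_nm2`); relative series paths are
#'   resolved against the metadata file's directory
#' @param burnin fraction of each series discarded as pre-equilibration
#' @return list of `window_series`
#' @export
read_windows <- function(metadata_file, burnin = 0.25) {
  if (!file.exists(metadata_file))
    stop("window metadata file not found: ", metadata_file)
  meta <- utils::read.table(metadata_file, header = FALSE,
                            col.names = c("path", "center", "k"),
                            stringsAsFactors = FALSE)
  base <- dirname(metadata_file)
  lapply(seq_len(nrow(meta)), function(i) {
    p <- meta$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    d <- utils::read.table(p, header = FALSE)
    samples <- d[[2]]
    spec <- window_spec(meta$center[i], k = meta$k[i],
                        n_samples = length(samples), burnin = burnin)
    n_burn <- floor(burnin * length(samples))
    structure(list(spec = spec, samples = samples, n_burnin = n_burn,
                   retained = if (n_burn > 0) samples[-seq_len(n_burn)] else samples),
              class = "window_series")
  })
}

#' Write / read alchemical perturbation-energy tables
#'
#' Tab-separated, one row per sample:
#' `lambda_from  lambda_to  direction  dU_kBT`.
#'
#' @param leg an [`alch_leg`][sample_alchemical]
#' @param file output path
#' @return `file`, invisibly
#' @export
write_alchemical <- function(leg, file) {
  stopifnot(inherits(leg, "alch_leg"))
  n_pair <- length(leg$lambdas) - 1
  rows <- do.call(rbind, lapply(seq_len(n_pair), function(i) {
    rbind(data.frame(lambda_from = leg$lambdas[i],
                     lambda_to = leg$lambdas[i + 1],
                     direction = "forward", dU_kBT = leg$forward[[i]]),
          data.frame(lambda_from = leg$lambdas[i + 1],
                     lambda_to = leg$lambdas[i],
                     direction = "backward", dU_kBT = leg$backward[[i]]))
  }))
  utils::write.table(rows, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_alchemical
#' @param environment leg environment label for the reconstructed object
#' @return for `read_alchemical`, an `alch_leg`
#' @export
read_alchemical <- function(file, environment = c("protein", "solution")) {
  environment <- match.arg(environment)
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  lams <- sort(unique(c(d$lambda_from, d$lambda_to)))
  n_pair <- length(lams) - 1
  fwd <- vector("list", n_pair); bwd <- vector("list", n_pair)
  for (i in seq_len(n_pair)) {
    fwd[[i]] <- d$dU_kBT[d$direction == "forward" &
                           abs(d$lambda_from - lams[i]) < 1e-9]
    bwd[[i]] <- d$dU_kBT[d$direction == "backward" &
                           abs(d$lambda_from - lams[i + 1]) < 1e-9]
    if (length(fwd[[i]]) < 2 || length(bwd[[i]]) < 2)
      stop("lambda pair ", lams[i], " -> ", lams[i + 1],
           " lacks samples in one direction")
  }
  structure(list(lambdas = lams, environment = environment,
                 forward = fwd, backward = bwd,
                 increments = NULL, sigma = NULL),
            class = "alch_leg")
}

#' Write a PMF profile table
#'
#' Tab-separated `coord_A  G_kBT  sigma_kBT  n_samples`.
#'
#' @param pmf a `pmf_profile`
#' @param file output path
#' @return `file`, invisibly
#' @export
write_pmf <- function(pmf, file) {
  utils::write.table(as.data.frame(pmf), file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' @rdname write_pmf
#' @return for `read_pmf`, a `pmf_profile` (window metadata absent)
#' @export
read_pmf <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t")
  need <- c("coord_A", "G_kBT", "sigma_kBT", "n_samples")
  if (!all(need %in% names(d)))
    stop("PMF table must have columns: ", paste(need, collapse = ", "))
  if (nrow(d) < 3 || is.unsorted(d$coord_A, strictly = TRUE))
    stop("PMF table needs >= 3 rows with strictly increasing coord_A")
  bw <- stats::median(diff(d$coord_A))
  structure(list(grid = d$coord_A, G = d$G_kBT, sigma = d$sigma_kBT,
                 n_samples = d$n_samples, bin_width = bw, zero = "none",
                 f = NA_real_, iterations = NA_integer_,
                 residual = NA_real_,
                 windows = list(centers = numeric(0), k = numeric(0))),
            class = "pmf_profile")
}

#' Write a result object as JSON
#'
#' Serializes `barrier_summary`, `cycle_result`, `selection_energetics` or
#' `fidelity_result` objects (and plain lists) to pretty-printed JSON.
#'
#' @param x object to serialize
#' @param file output path
#' @return `file`, invisibly
#' @export
write_result_json <- function(x, file) {
  if (inherits(x, "barrier_summary"))
    x <- list(pre_min = as.list(x$pre_min), ts_max = as.list(x$ts_max),
              ins_min = as.list(x$ins_min), dE_in = x$dE_in,
              dE_rev = x$dE_rev, dG_end = x$dG_end,
              monotone = x$monotone)
  else if (inherits(x, "cycle_result"))
    x <- list(ddG_b = x$ddG_b, se = x$se, dG_pro = x$dG_pro,
              dG_sol = x$dG_sol)
  else if (inherits(x, "fidelity_result"))
    x <- list(populations = as.list(x$populations), J_c = x$J_c,
              J_nc = x$J_nc, J = x$J, err = x$err)
  else if (inherits(x, "selection_energetics"))
    x <- unclass(x)
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(file)
}
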