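# Configuration files, TSV logs and snapshots, run manifests, and the
# hand-built fixture genomes used throughout the tests and examples.

configFields <- c(
  "popSize", "nHidden", "initWeightRange", "omega",
  "resourceValues", "signals", "suitabilityThreshold",
  "phi", "eps", "abruptness",
  "crossoverPerLocus", "pointMutPerAllele", "perturbRange", "alleleRange",
  "matingMutRate",
  "matingMutStart", "mutStop", "endGen",
  "aDominant", "strictP0", "retainCrossover", "snapshotEvery", "seed")

#' Convert a configuration to a flat named list
#' @param config a [SimulationConfig-class].
#' @return named list with one entry per configuration field (signal matrix
#'   flattened row-wise).
#' @export
configToList <- function(config) {
  env <- config@environment
  list(popSize = config@popSize, nHidden = config@nHidden,
       initWeightRange = config@initWeightRange, omega = config@omega,
       resourceValues = resourceValues(env),
       signals = as.vector(t(signalSet(env))),
       suitabilityThreshold = env@suitabilityThreshold,
       phi = config@ecology@phi, eps = config@ecology@eps,
       abruptness = config@ecology@abruptness,
       crossoverPerLocus = config@rates@crossoverPerLocus,
       pointMutPerAllele = config@rates@pointMutPerAllele,
       perturbRange = config@rates@perturbRange,
       alleleRange = config@rates@alleleRange,
       matingMutRate = config@rates@matingMutRate,
       matingMutStart = config@matingMutStart, mutStop = config@mutStop,
       endGen = config@endGen, aDominant = config@aDominant,
       strictP0 = config@strictP0, retainCrossover = config@retainCrossover,
       snapshotEvery = config@snapshotEvery, seed = config@seed)
}

#' Build a configuration from a flat named list
#'
#' Unspecified fields take the reference defaults; unknown fields and
#' out-of-range values raise validation errors naming the field.
#'
#' @param lst named list of configuration fields (see [configToList()]).
#' @return a [SimulationConfig-class].
#' @export
configFromList <- function(lst) {
  unknown <- setdiff(names(lst), configFields)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  d <- configToList(simulationConfig())
  d[names(lst)] <- lst
  sig <- matrix(as.numeric(unlist(d$signals)), ncol = 2, byrow = TRUE)
  env <- tryCatch(
    simEnvironment(d$resourceValues, sig, d$suitabilityThreshold),
    error = function(e) stop("invalid environment: ", conditionMessage(e)))
  eco <- tryCatch(
    ecologyParams(d$phi, d$eps, d$abruptness),
    error = function(e) stop("invalid ecology parameters: ",
                             conditionMessage(e)))
  rates <- tryCatch(
    mutationRates(d$crossoverPerLocus, d$pointMutPerAllele,
                  unlist(d$perturbRange), unlist(d$alleleRange),
                  d$matingMutRate),
    error = function(e) stop("invalid mutation rates: ",
                             conditionMessage(e)))
  simulationConfig(popSize = d$popSize, nHidden = d$nHidden,
                   initWeightRange = unlist(d$initWeightRange),
                   omega = d$omega, environment = env, ecology = eco,
                   rates = rates, matingMutStart = d$matingMutStart,
                   mutStop = d$mutStop, endGen = d$endGen,
                   aDominant = d$aDominant, strictP0 = d$strictP0,
                   retainCrossover = d$retainCrossover,
                   snapshotEvery = d$snapshotEvery, seed = d$seed)
}

#' Load a configuration from a YAML file
#'
#' The file is a flat key-value document; any subset of fields may be given
#' (an empty document yields the full reference defaults).
#'
#' @param path path to a YAML file, or NULL for pure defaults.
#' @return a validated [SimulationConfig-class].
#' @export
loadConfig <- function(path = NULL) {
  if (is.null(path)) return(simulationConfig())
  if (!file.exists(path)) stop("config file not found: ", path)
  lst <- yaml::read_yaml(path)
  if (is.null(lst)) lst <- list()
  configFromList(lst)
}

#' Save a configuration to a YAML file
#' @param config a [SimulationConfig-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
saveConfig <- function(config, path) {
  yaml::write_yaml(configToList(config), path, precision = 17)
  invisible(path)
}

# snapshots -------------------------------------------------------------------

snapshotHeader <- function(nHidden = 3L) {
  ln <- locusNames(nHidden)
  c("id", paste0("h1_", ln), paste0("h2_", ln), "mat1", "mat2")
}

#' Write a population snapshot as TSV
#'
#' One row per individual: id, all alleles of haplotype 1 in locus order, all
#' alleles of haplotype 2, and the two mating alleles as characters r/a.
#' Allele values are written with round-trippable precision.
#'
#' @param pop an [ExploiterPop-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSnapshot <- function(pop, path) {
  n <- nInd(pop)
  h <- (ncol(pop@hapA) - 1L) %/% 4L
  fmt <- function(m) apply(m, 2, function(x) sprintf("%.17g", x))
  rows <- cbind(id = as.character(seq_len(n)),
                fmt(pop@hapA), fmt(pop@hapB),
                mat1 = pop@matA, mat2 = pop@matB)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(snapshotHeader(h), collapse = "\t"), con)
  writeLines(apply(rows, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a population snapshot from TSV
#'
#' Inverse of [writeSnapshot()]; malformed rows raise an error reporting the
#' offending line number.
#'
#' @param path snapshot TSV path.
#' @return an [ExploiterPop-class].
#' @export
readSnapshot <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty snapshot file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nc <- length(fields[[1L]])
  if (nc < 5L || (nc - 5L) %% 8L != 0L)
    stop("malformed snapshot header: ", nc, " columns")
  L <- (nc - 3L) %/% 2L
  bad <- which(lengths(fields) != nc)
  if (length(bad))
    stop("malformed snapshot row at line ", bad[1L],
         ": expected ", nc, " fields, found ", lengths(fields)[bad[1L]])
  n <- length(lines) - 1L
  if (n == 0L)
    return(exploiterPop(matrix(numeric(0), 0, L), matrix(numeric(0), 0, L),
                        character(0), character(0)))
  body <- matrix(unlist(fields[-1L]), nrow = n, byrow = TRUE)
  hapA <- matrix(as.numeric(body[, 1L + seq_len(L)]), n, L)
  hapB <- matrix(as.numeric(body[, 1L + L + seq_len(L)]), n, L)
  if (any(is.na(hapA)) || any(is.na(hapB)))
    stop("non-numeric allele value in snapshot: ", path)
  exploiterPop(hapA, hapB, matA = body[, nc - 1L], matB = body[, nc])
}

# generation log --------------------------------------------------------------

#' Write the per-generation record table as TSV
#' @param recs data.frame of generation records (see [generationRecord()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenerationLog <- function(recs, path) {
  out <- recs
  for (j in which(vapply(out, is.double, logical(1))))
    out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-generation record table from TSV
#' @param path log TSV path.
#' @return data.frame of generation records.
#' @export
readGenerationLog <- function(path) {
  lines <- readLines(path)
  nc <- length(strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]])
  bad <- which(lengths(strsplit(lines, "\t", fixed = TRUE)) != nc)
  if (length(bad))
    stop("malformed log row at line ", bad[1L])
  utils::read.delim(path, check.names = FALSE)
}

#' Write all outputs of a run to a directory
#'
#' Produces `generations.tsv`, one `snapshot_<gen>.tsv` per stored snapshot,
#' `config.yaml`, and `manifest.yaml` (seed, package version, termination
#' reason, and file inventory) — enough to reproduce the run bit-for-bit.
#'
#' @param result a [SimulationResult-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeRunOutputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGenerationLog(records(result), file.path(dir, "generations.tsv"))
  snapFiles <- character(0)
  for (g in names(snapshots(result))) {
    f <- sprintf("snapshot_%s.tsv", g)
    writeSnapshot(snapshots(result)[[g]], file.path(dir, f))
    snapFiles <- c(snapFiles, f)
  }
  saveConfig(result@config, file.path(dir, "config.yaml"))
  manifest <- list(
    seed = result@seed,
    package = "perceptsim",
    version = as.character(utils::packageVersion("perceptsim")),
    termination = result@termination,
    files = c("generations.tsv", "config.yaml", snapFiles))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

# fixtures --------------------------------------------------------------------

#' Hand-built fixture genomes with known phenotypes
#'
#' Deterministic weight sets whose rounded response arrays under the default
#' four-niche signal set are known by construction:
#' \describe{
#'   \item{specialist1}{homozygote expressing class `[1,0,0,0]` — hidden node
#'     1 switches at s1 = 0.3 (weights w11 = -20, bh1 = -6, wout1 = 20,
#'     bo = 10, all other weights 0).}
#'   \item{specialist3}{homozygote expressing class `[0,0,1,0]` — two hidden
#'     nodes bracket the niche-III signal.}
#'   \item{generalist}{homozygote expressing `[1,1,1,1]` (all weights 0,
#'     bo = -10, so the output node is constitutively excited).}
#'   \item{heterozygote-like}{two different haplotypes (the specialist1
#'     haplotype over the null haplotype) whose codominant average still
#'     expresses `[1,0,0,0]`.}
#' }
#'
#' @param kind one of `"specialist1"`, `"specialist3"`, `"generalist"`,
#'   `"heterozygote-like"`.
#' @param n number of copies (default 1; 0 gives an empty population).
#' @param matA,matB mating alleles for every copy (default "r").
#' @return an [ExploiterPop-class] of `n` identical genomes.
#' @examples
#' phenotypeLabels(classifyPhenotype(
#'   responseArray(fixtureGenomes("specialist3", 1), simEnvironment())))
#' @export
fixtureGenomes <- function(kind = c("specialist1", "specialist3",
                                    "generalist", "heterozygote-like"),
                           n = 1L, matA = "r", matB = "r") {
  kind <- match.arg(kind)
  ln <- locusNames(3L)
  zero <- stats::setNames(numeric(13L), ln)
  hap <- function(...) { v <- zero; v[names(list(...))] <- unlist(list(...)); v }
  s1 <- hap(w11 = -20, bh1 = -6, wout1 = 20, bo = 10)
  s3 <- hap(w11 = 20, bh1 = 10, wout1 = 20,
            w12 = 20, bh2 = 14, wout2 = -40, bo = 10)
  gen <- hap(bo = -10)
  pair <- switch(kind,
    "specialist1" = list(s1, s1),
    "specialist3" = list(s3, s3),
    "generalist" = list(gen, gen),
    "heterozygote-like" = list(s1, zero))
  n <- as.integer(n)
  rows <- function(v) if (n == 0L)
    matrix(numeric(0), 0L, 13L, dimnames = list(NULL, ln))
  else matrix(v, n, 13L, byrow = TRUE, dimnames = list(NULL, ln))
  exploiterPop(rows(pair[[1]]), rows(pair[[2]]), matA = matA, matB = matB)
}
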