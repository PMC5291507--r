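# Named substreams derived from one master seed, so that (say) regenerating the
# topology does not perturb the noise stream of the run itself.
.seed_offsets <- c(topology = 101L, zones = 211L, run = 307L, pose = 401L)

#' Derive a named substream seed from a master seed
#'
#' One master seed fans out deterministically to independent substreams for
#' topology construction, zone assignment, the simulation run (noise and
#' inter-trial delays) and the robot's initial pose. Changing which substream a
#' component uses leaves all other components bit-reproducible.
#'
#' @param seed Master seed (integer).
#' @param what One of `"topology"`, `"zones"`, `"run"`, `"pose"`.
#' @return An integer seed below 2^31.
#' @export
#' @examples
#' seed_for(42, "topology")
seed_for <- function(seed, what = c("topology", "zones", "run", "pose")) {
  what <- match.arg(what)
  seed <- as.numeric(seed)
  as.integer((seed * 48271 + .seed_offsets[[what]]) %% 2147483647)
}
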