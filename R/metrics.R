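# Behavioral coordination metrics for via-point trajectories: Savitzky-Golay
# preprocessing, minimum via-point distances and crossing times, per-trial
# strategy and dyad classification, leadership indices, learner flags and
# per-epoch collaboration probabilities.

#' Savitzky-Golay smoothing with derivatives
#'
#' Local least-squares polynomial smoothing of a uniformly sampled signal;
#' velocity and acceleration come from the same local fit. Defaults follow
#' common practice for 100 Hz planar reaching data: 4th-order fit over a
#' 370 ms window.
#'
#' @param x numeric vector (one coordinate).
#' @param fs sampling rate (Hz).
#' @param window window length in seconds (rounded to an odd sample count).
#' @param order polynomial order.
#' @return data.frame with columns `pos`, `vel`, `acc`.
#' @export
sg_smooth <- function(x, fs = 100, window = 0.37, order = 4) {
  n <- round(window * fs)
  if (n %% 2 == 0) n <- n + 1
  if (n <= order + 1) stop("window too short for the polynomial order")
  if (length(x) < n) stop("signal shorter than the smoothing window")
  ts <- 1 / fs
  data.frame(pos = signal::sgolayfilt(x, p = order, n = n, m = 0),
             vel = signal::sgolayfilt(x, p = order, n = n, m = 1, ts = ts),
             acc = signal::sgolayfilt(x, p = order, n = n, m = 2, ts = ts))
}

#' Minimum via-point distance and crossing time
#'
#' MD = the closest approach of a sampled path to a via-point; TC = the time
#' of that minimum (first occurrence on ties).
#'
#' @param traj data.frame with columns t, x, y.
#' @param vp via-point position c(x, y).
#' @return list (MD, TC).
#' @export
min_vp_distance <- function(traj, vp) {
  d <- sqrt((traj$x - vp[1])^2 + (traj$y - vp[2])^2)
  i <- which.min(d)
  list(MD = d[i], TC = traj$t[i])
}

#' Classify one player's per-trial crossing strategy
#'
#' E = crosses own then partner's via-point; L = partner's then own;
#' M = crosses only the own via-point (ignores the partner); `invalid` when
#' the own via-point is missed (a case the E/M/L rule does not cover).
#' Thresholds are strict ("below d").
#'
#' @param MD_own,MD_other minimum distances to the own / partner via-point (m).
#' @param TC_own,TC_other corresponding crossing times (s).
#' @param d distance threshold (default 0.02 m).
#' @return one of "E", "M", "L", "invalid".
#' @export
classify_strategy <- function(MD_own, MD_other, TC_own = NA, TC_other = NA,
                              d = 0.02) {
  if (!(MD_own < d)) return("invalid")
  if (!(MD_other < d)) return("M")
  if (TC_own < TC_other) "E" else "L"
}

#' Classify a dyad's per-trial coordination
#'
#' Collaborative when the players take complementary orders (E-L or L-E);
#' cyclic when both take the same order (E-E or L-L); non-collaborative
#' otherwise (any M or invalid).
#'
#' @param s1,s2 the two players' strategy labels.
#' @return one of "collaborative", "cyclic", "non-collaborative".
#' @export
classify_dyad <- function(s1, s2) {
  if ((s1 == "E" && s2 == "L") || (s1 == "L" && s2 == "E")) return("collaborative")
  if ((s1 == "E" && s2 == "E") || (s1 == "L" && s2 == "L")) return("cyclic")
  "non-collaborative"
}

#' Leadership index at a via-point crossing
#'
#' Mean mechanical power of the interaction force on the player (inner
#' product of interaction force and hand velocity) over the window just
#' before the crossing time. A leader moves against the coupling spring
#' (negative power); a follower is pulled along by it (positive power).
#'
#' @param F_int n x 2 matrix of interaction-force samples (N).
#' @param vel n x 2 matrix of velocity samples (m/s).
#' @param t sample times (s).
#' @param TC crossing time (s).
#' @param window averaging window length before TC (default 0.3 s).
#' @param signed if FALSE, use the signed squared-magnitude projection of the
#'   force on the velocity direction instead of mechanical power (alternative
#'   convention).
#' @return scalar leadership index (W for the power convention).
#' @export
leadership_index <- function(F_int, vel, t, TC, window = 0.3, signed = TRUE) {
  idx <- which(t >= TC - window & t < TC)
  if (length(idx) == 0L) return(NA_real_)
  if (signed) {
    mean(F_int[idx, 1] * vel[idx, 1] + F_int[idx, 2] * vel[idx, 2])
  } else {
    sp <- rowSums(vel[idx, , drop = FALSE]^2)
    proj <- (F_int[idx, 1] * vel[idx, 1] + F_int[idx, 2] * vel[idx, 2]) /
      sqrt(pmax(sp, 1e-12))
    mean(sign(proj) * proj^2)
  }
}

#' Learner classification from end-of-training performance
#'
#' A player is a learner when their mean minimum distance to the partner's
#' via-point over the final training epoch is below the threshold (strict).
#'
#' @param MD_other per-trial minimum distances to the partner's via-point (m).
#' @param epoch_size trials per epoch (default 12).
#' @param threshold learner threshold (default 0.02 m).
#' @return logical.
#' @export
learner_flag <- function(MD_other, epoch_size = 12, threshold = 0.02) {
  n <- length(MD_other)
  if (n < epoch_size) stop("series shorter than one epoch")
  last <- MD_other[(n - epoch_size + 1L):n]
  mean(last) < threshold
}

#' Per-epoch collaboration probabilities
#'
#' Tabulates, per consecutive epoch, the relative frequency of collaborative,
#' cyclic and non-collaborative trials (a final partial epoch is dropped).
#'
#' @param s1,s2 per-trial strategy labels of the two players.
#' @param epoch_size trials per epoch (default 12).
#' @return matrix (epochs x 3), columns collaborative/cyclic/non-collaborative;
#'   rows sum to 1.
#' @export
collaboration_probability <- function(s1, s2, epoch_size = 12) {
  stopifnot(length(s1) == length(s2))
  lab <- mapply(classify_dyad, s1, s2)
  n_ep <- length(lab) %/% epoch_size
  if (n_ep < 1L) stop("series shorter than one epoch")
  lev <- c("collaborative", "cyclic", "non-collaborative")
  out <- matrix(0, n_ep, 3L, dimnames = list(NULL, lev))
  for (e in seq_len(n_ep)) {
    idx <- ((e - 1L) * epoch_size + 1L):(e * epoch_size)
    out[e, ] <- as.numeric(table(factor(lab[idx], levels = lev))) / epoch_size
  }
  out
}

#' Full per-trial metric table for recorded or simulated 2-VP data
#'
#' Consumes the tidy trajectory table (columns trial, player, t, x, y, Fx,
#' Fy — the shape produced by [viapoint_recordings()] or recorded at 100 Hz)
#' and computes, per trial and player: minimum distances and crossing times
#' to both via-points, the E/M/L strategy, leadership indices at both
#' via-points, and the dyad classification.
#'
#' @param traj tidy trajectory table.
#' @param VP1,VP2 via-point positions (m).
#' @param d strategy threshold (m).
#' @param smooth if TRUE, Savitzky-Golay smooth positions (and derive
#'   velocities from the fit); otherwise use finite-difference velocities.
#' @param fs sampling rate (Hz), used for smoothing and derivatives.
#' @return data.frame, one row per (trial, player), with MD/TC to both VPs,
#'   strategy `s`, LI at both VPs, and the per-trial dyad label.
#' @export
coordination_metrics <- function(traj, VP1, VP2, d = 0.02, smooth = TRUE,
                                 fs = 100) {
  vps <- list(VP1, VP2)
  res <- list()
  for (tr in sort(unique(traj$trial))) {
    sub <- traj[traj$trial == tr, ]
    per <- list()
    for (i in 1:2) {
      pi_ <- sub[sub$player == i, ]
      pi_ <- pi_[order(pi_$t), ]
      if (smooth && nrow(pi_) >= 41L) {
        sx <- sg_smooth(pi_$x, fs = fs); sy <- sg_smooth(pi_$y, fs = fs)
        px <- sx$pos; py <- sy$pos; vel <- cbind(sx$vel, sy$vel)
      } else {
        px <- pi_$x; py <- pi_$y
        vel <- cbind(c(0, diff(px)) * fs, c(0, diff(py)) * fs)
      }
      tt <- pi_$t
      md <- lapply(vps, function(vp) min_vp_distance(data.frame(t = tt, x = px, y = py), vp))
      Fm <- cbind(pi_$Fx, pi_$Fy)
      li <- vapply(1:2, function(j)
        leadership_index(Fm, vel, tt, md[[j]]$TC), numeric(1))
      per[[i]] <- data.frame(
        trial = tr, player = i,
        MD1 = md[[1]]$MD, TC1 = md[[1]]$TC, MD2 = md[[2]]$MD, TC2 = md[[2]]$TC,
        LI1 = li[1], LI2 = li[2])
    }
    for (i in 1:2) {
      own <- i; oth <- 3L - i
      per[[i]]$MD_own <- per[[i]][[paste0("MD", own)]]
      per[[i]]$MD_other <- per[[i]][[paste0("MD", oth)]]
      per[[i]]$s <- classify_strategy(per[[i]]$MD_own, per[[i]]$MD_other,
                                      per[[i]][[paste0("TC", own)]],
                                      per[[i]][[paste0("TC", oth)]], d = d)
    }
    dy <- classify_dyad(per[[1]]$s, per[[2]]$s)
    per[[1]]$dyad <- dy; per[[2]]$dyad <- dy
    res[[length(res) + 1L]] <- rbind(per[[1]], per[[2]])
  }
  do.call(rbind, res)
}
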