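# Finite-difference Lagrangian oracle: assembles the equations of motion
# numerically from T(q, qd), V(q), the Rayleigh dissipation D(q, qd), and
# the applied-point Jacobian, independently of the closed-form derivative.
# q-direction steps kept moderate to balance truncation vs roundoff.
oracle_accel <- function(state, efforts, params, treat) {
  p <- apply_treatment(params, treat)
  q <- as.numeric(state[1:4]); qd <- as.numeric(state[5:8])
  vel1 <- function(q, qd) c(qd[1], qd[2])
  vel2 <- function(q, qd) c(qd[1] + p$L1*sin(q[3])*qd[3] - p$L2*sin(q[4])*qd[4],
                            qd[2] - p$L1*cos(q[3])*qd[3] + p$L2*cos(q[4])*qd[4])
  Tfun <- function(q, qd) {
    v1 <- vel1(q, qd); v2 <- vel2(q, qd)
    0.5*p$m1*sum(v1^2) + 0.5*p$m2*sum(v2^2) + 0.5*p$I1*qd[3]^2 + 0.5*p$I2*qd[4]^2
  }
  Vfun <- function(q) {
    b <- q[4]-q[3]-pi; wb <- b - 2*pi*round(b/(2*pi))
    p$m1*p$g*q[2] + p$m2*p$g*(q[2]-p$L1*sin(q[3])+p$L2*sin(q[4])) + 0.5*p$kappa*wb^2
  }
  Dfun <- function(q, qd) {
    v1 <- vel1(q, qd); v2 <- vel2(q, qd)
    d <- 0.5*p$eta*(qd[4]-qd[3])^2
    if (p$drag == "quadratic") {
      d <- d + (p$rho_a*p$Cd*pi*p$r1^2/6)*sum(v1^2)^1.5 + (p$rho_a*p$Cd*pi*p$r2^2/6)*sum(v2^2)^1.5
    } else if (p$drag == "linear") {
      d <- d + 3*pi*p$mu_a*p$r1*sum(v1^2) + 3*pi*p$mu_a*p$r2*sum(v2^2)
    }
    d
  }
  hq <- 1e-4; hv <- 1e-2
  # mass matrix M_ij = d2T/dqd_i dqd_j (T quadratic in qd: FD exact)
  M <- matrix(0,4,4)
  for (i in 1:4) for (j in 1:4) {
    ei <- numeric(4); ei[i] <- hv; ej <- numeric(4); ej[j] <- hv
    M[i,j] <- (Tfun(q, qd+ei+ej) - Tfun(q, qd+ei-ej) - Tfun(q, qd-ei+ej) + Tfun(q, qd-ei-ej))/(4*hv^2)
  }
  # c_i = sum_j d2T/(dq_j dqd_i) qd_j - dT/dq_i
  cvec <- numeric(4)
  for (i in 1:4) {
    s <- 0
    for (j in 1:4) {
      ei <- numeric(4); ei[i] <- hv; ej <- numeric(4); ej[j] <- hq
      d2 <- (Tfun(q+ej, qd+ei) - Tfun(q+ej, qd-ei) - Tfun(q-ej, qd+ei) + Tfun(q-ej, qd-ei))/(4*hv*hq)
      s <- s + d2*qd[j]
    }
    ej <- function(i) { e <- numeric(4); e[i] <- hq; e }
    cvec[i] <- s - (Tfun(q+ej(i), qd) - Tfun(q-ej(i), qd))/(2*hq)
  }
  ej <- function(i) { e <- numeric(4); e[i] <- hq; e }
  ev <- function(i) { e <- numeric(4); e[i] <- hv; e }
  gvec <- sapply(1:4, function(i) (Vfun(q+ej(i)) - Vfun(q-ej(i)))/(2*hq))
  hd <- 1e-4
  ed <- function(i) { e <- numeric(4); e[i] <- hd; e }
  dvec <- sapply(1:4, function(i) (Dfun(q, qd+ed(i)) - Dfun(q, qd-ed(i)))/(2*hd))
  # applied efforts: force F at body-relative angle alpha, acting at a point
  # rigidly attached to body 1: generalized force = (F on x,y; moment of F
  # about the body-1 center on theta)
  Fm <- efforts[["F"]]; al <- efforts[["alpha"]]
  Fw <- Fm * c(cos(q[3]+al), sin(q[3]+al))
  r1 <- q[1:2]
  r2 <- c(q[1] - p$L1*cos(q[3]) + p$L2*cos(q[4]), q[2] - p$L1*sin(q[3]) + p$L2*sin(q[4]))
  P <- if (p$force_origin == "com") (p$m1*r1 + p$m2*r2)/(p$m1+p$m2) else r1
  if (is_shifted(treat)) P <- P + p$L3*c(cos(q[3]), sin(q[3]))
  arm <- P - r1
  Q <- c(Fw[1], Fw[2], arm[1]*Fw[2] - arm[2]*Fw[1], 0)
  Q[3] <- Q[3] + (if (wing_torque_active(treat)) efforts[["tau_wing"]] else 0) - efforts[["tau_abdo"]]
  Q[4] <- Q[4] + efforts[["tau_abdo"]]
  solve(M, Q - cvec - gvec - dvec)
}
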