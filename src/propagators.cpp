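#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Bloch-McConnell CEST profile for an n-state exchange model.
//
// Basis is (Mx, My, Mz) per state, 3n components in total.  The generator is
// homogeneous (relaxation decays towards zero, no R1 recovery term), so far
// off-resonance the profile tends to exp(-R1 * t_sat) exactly.
//
// pops        stationary populations (pA first), length n
// shifts_ppm  absolute chemical shift of each state, ppm
// r1          longitudinal rate shared by all states, 1/s
// r2          transverse rate per state, 1/s
// K           n x n first-order exchange matrix, columns sum to zero
// b1_hz       saturation field strength, Hz
// t_sat       saturation time, s
// f_mhz       Larmor frequency of the observed nucleus, MHz (Hz per ppm)
// offsets_ppm saturation carrier positions, ppm
//
// Returns I/I0 (major-state z magnetization normalized by its t_sat = 0
// value) at each offset.
// [[Rcpp::export]]
arma::vec bm_cest_cpp(const arma::vec& pops, const arma::vec& shifts_ppm,
                      double r1, const arma::vec& r2, const arma::mat& K,
                      double b1_hz, double t_sat, double f_mhz,
                      const arma::vec& offsets_ppm) {
    const uword n = pops.n_elem;
    const double w1 = 2.0 * M_PI * b1_hz;
    vec out(offsets_ppm.n_elem);
    mat L(3 * n, 3 * n);
    vec m0(3 * n, fill::zeros);
    for (uword s = 0; s < n; ++s) m0(3 * s + 2) = pops(s);

    for (uword k = 0; k < offsets_ppm.n_elem; ++k) {
        L.zeros();
        for (uword s = 0; s < n; ++s) {
            // offset of state s resonance from the saturation carrier, rad/s
            double dw = 2.0 * M_PI * f_mhz * (shifts_ppm(s) - offsets_ppm(k));
            uword i = 3 * s;
            L(i,     i)     = -r2(s); L(i,     i + 1) = -dw;
            L(i + 1, i)     =  dw;    L(i + 1, i + 1) = -r2(s);
            L(i + 1, i + 2) = -w1;
            L(i + 2, i + 1) =  w1;    L(i + 2, i + 2) = -r1;
        }
        for (uword a = 0; a < n; ++a)
            for (uword b = 0; b < n; ++b)
                if (K(a, b) != 0.0)
                    for (uword c = 0; c < 3; ++c)
                        L(3 * a + c, 3 * b + c) += K(a, b);
        vec m = expmat(L * t_sat) * m0;
        out(k) = m(2) / pops(0);
    }
    return out;
}

// Constant-time CPMG R2,eff for an n-state exchange model.
//
// Transverse magnetization is propagated in the complex single-quantum basis
// (one component per state).  Ideal, instantaneous 180-degree pulses act as
// complex conjugation; one echo block tau-180-2tau-180-tau therefore has the
// linear propagator  B = P(tau) * conj(P(2tau)) * P(tau).
//
// dshifts_ppm shift of each state relative to state A, ppm (first entry 0)
// nu          CPMG frequencies, Hz; nu = 1/(4 tau); t_relax * nu must be a
//             positive integer (number of echo blocks)
//
// Returns R2,eff per nu; a point is NaN when the detected major-state
// magnetization is not positive (underflow flag handled by the caller).
// [[Rcpp::export]]
arma::vec bm_cpmg_cpp(const arma::vec& pops, const arma::vec& dshifts_ppm,
                      const arma::vec& r2, const arma::mat& K,
                      double t_relax, double f_mhz, const arma::vec& nu) {
    const uword n = pops.n_elem;
    cx_mat Lam = conv_to<cx_mat>::from(K);
    for (uword s = 0; s < n; ++s)
        Lam(s, s) += cx_double(-r2(s), 2.0 * M_PI * f_mhz * dshifts_ppm(s));
    cx_vec m0 = conv_to<cx_vec>::from(pops);
    vec out(nu.n_elem);

    for (uword k = 0; k < nu.n_elem; ++k) {
        double tau = 1.0 / (4.0 * nu(k));
        int nblk = (int) std::lround(t_relax * nu(k));
        cx_mat P1 = expmat(Lam * tau);
        cx_mat P2 = expmat(Lam * (2.0 * tau));
        cx_mat B = P1 * conj(P2) * P1;
        cx_vec m = m0;
        for (int b = 0; b < nblk; ++b) m = B * m;
        double I = std::real(m(0));
        if (!std::isfinite(I) || I <= 0.0) {
            out(k) = datum::nan;
        } else {
            out(k) = std::log(pops(0) / I) / t_relax;
        }
    }
    return out;
}
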