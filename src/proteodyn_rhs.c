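/* Compiled derivative functions for the proteasome model family and the
 * two-cleavage-site polypeptide extension, used through deSolve's
 * compiled-model interface. Parameter layouts mirror pack_params() /
 * pack_poly_params() on the R side; the R ode_rhs() is the reference
 * implementation and the test suite holds the two equal. */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

/* ---- single-substrate family ------------------------------------------ */

#define NP_SINGLE 36
static double ps[NP_SINGLE];

void proteodyn_init_single(void (*odeparms)(int *, double *))
{
    int n = NP_SINGLE;
    odeparms(&n, ps);
}

static double clamp0(double x) { return x > 0 ? x : 0; }

/* two-site-modifier hydrolysis flux; lead is the precomputed leading
 * multiplicity (na or the number of active-site copies) */
static double vhydr_tsm(double S, double P, double lead, double kp,
                        double E0, double KaS, double KaP, double KiS,
                        double KiP, double na, double ni, double alpha,
                        double beta)
{
    double Sna = pow(S, na), Sni = pow(S, ni);
    double Pna = pow(P, na), Pni = pow(P, ni);
    double x = 1 + Sna / KaS + Sni / KiS + Pna / KaP + Pni / KiP
        + Sna * Sni / (alpha * KaS * KiS) + Pna * Pni / (alpha * KaP * KiP)
        + Sna * Pni / (alpha * KaS * KiP) + Sni * Pna / (alpha * KiS * KaP);
    return lead * kp * E0 * (Sna / KaS)
        * (1 + beta * Sni / (alpha * KiS) + beta * Pni / (alpha * KiP)) / x;
}

/* state layout: 0 Sout, 1 Pout, 2 G1, 3 G1Sout, 4 G1Pout, 5 S, 6 P,
 * 7 G2, 8 G2S, 9 G2P, 10 Ereg, 11 EregS, 12 EregP, 13 Ifree, 14 IS, 15 IP */
void proteodyn_deriv_single(int *neq, double *t, double *yy, double *ydot,
                            double *yout, int *ip)
{
    double y[16];
    int i;
    for (i = 0; i < 16; i++) y[i] = clamp0(yy[i]);
    for (i = 0; i < 16; i++) ydot[i] = 0;

    int cls = (int) ps[0], enh = (int) ps[1], inh = (int) ps[2];
    int diff = (int) ps[3];
    double lead = ps[4];
    double kon = ps[5], koff = ps[6], vin = ps[7], vout = ps[8], tau = ps[9];
    double C = ps[10], Ron = ps[11], Roff = ps[12], Xenh = ps[13];
    double Ion = ps[14], Ioff = ps[15], h = ps[16], Yinh = ps[17];
    double kp = ps[18], KaS = ps[19], KaP = ps[20], KiS = ps[21], KiP = ps[22];
    double na = ps[23], ni = ps[24], alpha = ps[25], beta = ps[26];
    double vmax = ps[27], KM = ps[28], eps_fb = ps[29], K_fb = ps[30];
    double E0 = ps[31], I0 = ps[32];

    double Sout = y[0], Pout = y[1];

    if (cls == 1) {                           /* Michaelis-Menten */
        double v = vmax * Sout / (KM + Sout);
        ydot[0] = -v; ydot[1] = v;
        return;
    }
    if (cls <= 4) {                           /* two-site modifier +- feedback */
        double fb = 1 + eps_fb * Pout / (K_fb + Pout);
        double KaS_eff = (cls == 3) ? KaS / fb : KaS;
        double kp_eff = (cls == 4) ? kp * fb : kp;
        double v = vhydr_tsm(Sout, Pout, lead, kp_eff, E0, KaS_eff, KaP,
                             KiS, KiP, na, ni, alpha, beta);
        ydot[0] = -v; ydot[1] = v;
        return;
    }

    /* compartmentalised transport skeleton */
    double S = y[5], P = y[6];
    double enhf = 1, inhf = 1;
    if (enh) enhf = 1 + Xenh * (y[11] + y[12]) / E0;
    if (inh) inhf = 1 + Yinh * (y[14] + y[15]) / I0;
    double capArg = E0 * C - S - P;
    double cap = tanh(capArg > 0 ? capArg : 0);
    double tin = vin * enhf / inhf * cap;
    double tout = vout * enhf / inhf;
    double vh = vhydr_tsm(S, P, lead, kp, E0, KaS, KaP, KiS, KiP,
                          na, ni, alpha, beta);

    if (diff) {                               /* free-diffusion variant */
        double inS = vin * cap * Sout, inP = vin * cap * Pout;
        double outS = vout * S, outP = vout * P;
        ydot[0] = -inS + outS; ydot[1] = -inP + outP;
        ydot[5] = inS - outS - vh; ydot[6] = inP - outP + vh;
        return;
    }

    double bS = kon * Sout * y[2], bP = kon * Pout * y[2];
    double uS = koff * y[3], uP = koff * y[4];
    double inS = tin * y[3], inP = tin * y[4];
    double trS = tau * S * y[7] / E0, trP = tau * P * y[7] / E0;
    double outS = tout * y[8], outP = tout * y[9];

    ydot[0] = -bS + uS + outS;
    ydot[1] = -bP + uP + outP;
    ydot[2] = -(bS + bP) + (uS + uP) + (inS + inP);
    ydot[3] = bS - uS - inS;
    ydot[4] = bP - uP - inP;
    ydot[5] = inS - trS - vh;
    ydot[6] = inP - trP + vh;
    ydot[7] = -(trS + trP) + (outS + outP);
    ydot[8] = trS - outS;
    ydot[9] = trP - outP;

    if (enh) {
        double eS = (enh == 2) ? S : Sout, eP = (enh == 2) ? P : Pout;
        double ebS = Ron * eS * y[10] / E0, ebP = Ron * eP * y[10] / E0;
        double euS = Roff * y[11], euP = Roff * y[12];
        ydot[10] = -(ebS + ebP) + (euS + euP);
        ydot[11] = ebS - euS;
        ydot[12] = ebP - euP;
        if (enh == 2) {
            ydot[5] += -ebS + euS; ydot[6] += -ebP + euP;
        } else {
            ydot[0] += -ebS + euS; ydot[1] += -ebP + euP;
        }
    }
    if (inh) {
        double iS = (inh == 2) ? Sout : S, iP = (inh == 2) ? Pout : P;
        double ibS = Ion * pow(iS, h) * y[13], ibP = Ion * pow(iP, h) * y[13];
        double iuS = Ioff * y[14], iuP = Ioff * y[15];
        ydot[13] = -(ibS + ibP) + (iuS + iuP);
        ydot[14] = ibS - iuS;
        ydot[15] = ibP - iuP;
        if (inh == 2) {
            ydot[0] += -h * ibS + h * iuS; ydot[1] += -h * ibP + h * iuP;
        } else {
            ydot[5] += -h * ibS + h * iuS; ydot[6] += -h * ibP + h * iuP;
        }
    }
}

/* ---- two-cleavage-site polypeptide ------------------------------------ */

/* fragments: 0 S (sites 1+2), 1 A, 2 BC (site 2), 3 AB (site 1), 4 B, 5 C.
 * state: [0..5] outer, [6..11] G1-bound, [12..17] inner, [18..23] G2-bound,
 * [24] free G1, [25] free G2.
 * parms: per fragment f: 5*f + (0 kon, 1 koff, 2 vin, 3 vout, 4 tau);
 * [30] E0, [31] C, [32] kp1, [33] kp2, [34] KaS, [35] KiS, [36] KiP,
 * [37] na, [38] ni, [39] alpha, [40] beta */
#define NP_POLY 41
static double pp[NP_POLY];

void proteodyn_init_poly(void (*odeparms)(int *, double *))
{
    int n = NP_POLY;
    odeparms(&n, pp);
}

void proteodyn_deriv_poly(int *neq, double *t, double *yy, double *ydot,
                          double *yout, int *ip)
{
    double y[26];
    int f, i;
    for (i = 0; i < 26; i++) y[i] = clamp0(yy[i]);
    for (i = 0; i < 26; i++) ydot[i] = 0;

    double E0 = pp[30], C = pp[31], kp1 = pp[32], kp2 = pp[33];
    double KaS = pp[34], KiS = pp[35], KiP = pp[36];
    double na = pp[37], ni = pp[38], alpha = pp[39], beta = pp[40];
    double G1 = y[24], G2 = y[25];

    double load = 0;
    for (f = 0; f < 6; f++) load += y[12 + f];
    double capArg = E0 * C - load;
    double cap = tanh(capArg > 0 ? capArg : 0);

    /* shared two-site-modifier law with species-summed occupancies;
     * cleavable: S (0), BC (2), AB (3); pure products: A (1), B (4), C (5) */
    static const int cleavable[6] = {1, 0, 1, 1, 0, 0};
    double a[6], asum = 0, bsum = 0;
    for (f = 0; f < 6; f++) {
        double X = y[12 + f];
        if (cleavable[f]) {
            a[f] = pow(X, na) / KaS;
            asum += a[f];
            bsum += pow(X, ni) / KiS;
        } else {
            a[f] = 0;
            bsum += pow(X, ni) / KiP;
        }
    }
    double x = 1 + asum + bsum + asum * bsum / alpha;
    double mod = (1 + beta * bsum / alpha) / x;
    /* per-fragment-per-site fluxes */
    double vS1 = na * kp1 * E0 * a[0] * mod;
    double vS2 = na * kp2 * E0 * a[0] * mod;
    double vBC2 = na * kp2 * E0 * a[2] * mod;
    double vAB1 = na * kp1 * E0 * a[3] * mod;

    for (f = 0; f < 6; f++) {
        double kon = pp[5 * f], koff = pp[5 * f + 1], vin = pp[5 * f + 2];
        double vout = pp[5 * f + 3], tau = pp[5 * f + 4];
        double b = kon * y[f] * G1, u = koff * y[6 + f];
        double in = vin * cap * y[6 + f];
        double tr = tau * y[12 + f] * G2 / E0;
        double out = vout * y[18 + f];
        ydot[f] += -b + u + out;
        ydot[6 + f] = b - u - in;
        ydot[12 + f] += in - tr;
        ydot[18 + f] = tr - out;
        ydot[24] += -b + u + in;
        ydot[25] += -tr + out;
    }

    /* cleavage stoichiometry (inner species) */
    ydot[12 + 0] += -vS1 - vS2;
    ydot[12 + 1] += vS1 + vAB1;
    ydot[12 + 2] += vS1 - vBC2;
    ydot[12 + 3] += vS2 - vAB1;
    ydot[12 + 4] += vBC2 + vAB1;
    ydot[12 + 5] += vS2 + vBC2;
}

static const R_CMethodDef cMethods[] = {
    {"proteodyn_init_single", (DL_FUNC) &proteodyn_init_single, 1},
    {"proteodyn_deriv_single", (DL_FUNC) &proteodyn_deriv_single, 6},
    {"proteodyn_init_poly", (DL_FUNC) &proteodyn_init_poly, 1},
    {"proteodyn_deriv_poly", (DL_FUNC) &proteodyn_deriv_poly, 6},
    {NULL, NULL, 0}
};

void R_init_proteodyn(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
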