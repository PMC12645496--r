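/* Compiled derivative field for the tumor / oncolytic-virus / PAC-1 / TRAIL
 * model, in the deSolve compiled-model interface.  Must stay in exact
 * agreement with the R reference gct_rhs(); the parameter packing order is
 * defined by pack_parms() in R/params.R.
 */
#include <R.h>
#include <math.h>

#define N_PARMS 47
static double parms[N_PARMS];

#define a1          parms[0]
#define a2          parms[1]
#define d2          parms[2]
#define d3          parms[3]
#define ktr         parms[4]
#define kappa       parms[5]
#define delta_      parms[6]
#define alpha_      parms[7]
#define omega_      parms[8]
#define kp          parms[9]
#define kQ          parms[10]
#define ks          parms[11]
#define psi_half    parms[12]
#define kcp         parms[13]
#define eta_half    parms[14]
#define C_half      parms[15]
#define gamma_P     parms[16]
#define Cprod_star  parms[17]
#define Cprod_max   parms[18]
#define k_elim      parms[19]
#define jpar        parms[20]
#define ka          parms[21]
#define V_PAC       parms[22]
#define kep         parms[23]
#define k12P        parms[24]
#define k21P        parms[25]
#define alpha_T     parms[26]
#define kel         parms[27]
#define kon         parms[28]
#define R0          parms[29]
#define k12         parms[30]
#define k21         parms[31]
#define Vol         parms[32]
#define kint        parms[33]
#define Tprod       parms[34]
#define Emax_PAC    parms[35]
#define Emax_TRAIL  parms[36]
#define gamma_PAC   parms[37]
#define gamma_TRAIL parms[38]
#define Psi         parms[39]
#define EC50_PAC    parms[40]
#define EC50_TRAIL  parms[41]
#define f_infection parms[42]
#define f_g1entry   parms[43]
#define f_ntotal    parms[44]
#define f_pdcomb    parms[45]
#define f_clip      parms[46]

void gctov_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

static double hill_c(double conc, double emax, double ec50, double gamma)
{
    double cg;
    if (conc <= 0.0) return 0.0;
    cg = pow(conc, gamma);
    return emax * cg / (pow(ec50, gamma) + cg);
}

void gctov_derivs(int *neq, double *t, double *y_, double *ydot,
                  double *yout, int *ip)
{
    int j = (int) (jpar + 0.5);
    int i;
    double y[64];
    double Q, G1, I, Vv, C, P, PA, PPAC, Pe, Tf, TP, TA;
    double E, EP, ET, haz, killQ, killS, lossA, N, target, entryA1, Cprod;
    double *A;

    for (i = 0; i < *neq; i++) {
        y[i] = y_[i];
        if (f_clip > 0.5 && y[i] < 0.0) y[i] = 0.0;
    }
    Q = y[0]; G1 = y[1];
    A = y + 2;
    I = y[2 + j]; Vv = y[3 + j]; C = y[4 + j]; P = y[5 + j];
    PA = y[6 + j]; PPAC = y[7 + j]; Pe = y[8 + j];
    Tf = y[9 + j]; TP = y[10 + j]; TA = y[11 + j];

    EP = hill_c(PPAC, Emax_PAC, EC50_PAC, gamma_PAC);
    ET = hill_c(Tf, Emax_TRAIL, EC50_TRAIL, gamma_TRAIL);
    if (f_pdcomb < 0.5)       E = EP + ET + Psi * EP * ET;
    else if (f_pdcomb < 1.5)  E = EP + ET - EP * ET;
    else                      E = EP;

    haz = kappa * Vv / (eta_half + Vv);
    killQ = kp * P / (1.0 + kQ * Q);
    killS = kp * P / (1.0 + ks * G1);
    lossA = d3 * (1.0 + E) + haz + killS;

    if (f_ntotal > 0.5) {
        N = 0.0;
        for (i = 0; i < j; i++) N += A[i];
    } else {
        N = y[12 + j];
    }
    target = (f_infection > 0.5) ? (G1 + N) : (G1 - N);
    entryA1 = (f_g1entry > 0.5) ? (a2 * G1) : (a1 * G1);

    ydot[0] = 2.0 * ktr * A[j - 1] - a1 * Q - killQ * Q;
    ydot[1] = a1 * Q - (a2 + d2 * (1.0 + E) + haz + killS) * G1;
    ydot[2] = entryA1 - ktr * A[0] - lossA * A[0];
    for (i = 1; i < j; i++)
        ydot[2 + i] = ktr * (A[i - 1] - A[i]) - lossA * A[i];

    ydot[2 + j] = haz * target - delta_ * I;
    ydot[3 + j] = alpha_ * delta_ * I - omega_ * Vv - haz * target;
    Cprod = Cprod_star + (Cprod_max - Cprod_star) * I / (psi_half + I);
    ydot[4 + j] = Cprod - k_elim * C;
    ydot[5 + j] = kcp * C / (C_half + C) - gamma_P * P;
    ydot[6 + j] = -ka * PA;
    ydot[7 + j] = ka * PA / V_PAC - (kep + k12P) * PPAC + k21P * Pe;
    ydot[8 + j] = k12P * PPAC - k21P * Pe;
    ydot[9 + j] = alpha_T * delta_ * I - kel * Tf - kon * Tf * (R0 - TP)
                  - k12 * Tf + k21 * TA / Vol + Tprod;
    ydot[10 + j] = kon * (R0 - TP) * Tf - kint * TP;
    ydot[11 + j] = k12 * Vol * Tf - k21 * TA;

    if (f_ntotal < 0.5)
        ydot[12 + j] = a2 * G1 - ktr * A[j - 1] - lossA * N;
}
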